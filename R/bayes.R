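# Bayesian GWAS-eQTL integration: eSNP discovery, per-SNP approximate Bayes
# factors against the GWAS, per-gene log-Bayes-factor aggregation, and
# permutation-based simulated p-values.

#' Identify expression-associated SNPs (eSNPs)
#'
#' Keeps (SNP, gene) pairs with `p_eqtl <= p_threshold` (boundary inclusive);
#' duplicated pairs are collapsed keeping the smallest p.
#'
#' @param eqtl eQTL data.frame with `rsid`, `gene_id`, `pvalue`.
#' @param p_threshold eSNP significance threshold, in (0, 1).
#' @return data.frame `rsid, gene_id, p_eqtl`.
#' @export
identify_esnps <- function(eqtl, p_threshold = 1e-4) {
  check_scalar_prob(p_threshold, "p_threshold")
  d <- eqtl[eqtl$pvalue <= p_threshold, c("rsid", "gene_id", "pvalue"), drop = FALSE]
  names(d)[3] <- "p_eqtl"
  if (nrow(d) == 0) return(d)
  d <- d[order(d$p_eqtl), , drop = FALSE]
  d <- d[!duplicated(d[c("rsid", "gene_id")]), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Log Bayes factor of association for one GWAS z-score
#'
#' Wakefield-style approximate Bayes factor on the unit-se z scale with
#' prior effect variance `W`:
#' `ln BF = 0.5 * ln(1 / (1 + W)) + (z^2 / 2) * W / (1 + W)`.
#' Strictly increasing in `z^2` and negative at `z = 0`, so GWAS-significant
#' eSNPs contribute positive scores and null eSNPs negative ones — the two
#' scored scenarios of the integration; SNPs that are not eSNPs are never
#' scored at all.
#'
#' @param z_gwas GWAS z-score(s); finite.
#' @param prior_w prior variance of the standardized effect (> 0).
#' @return natural-log Bayes factor(s), same length as `z_gwas`.
#' @export
snp_log_bayes_factor <- function(z_gwas, prior_w = 0.1) {
  if (!is.numeric(prior_w) || length(prior_w) != 1L || prior_w <= 0) {
    fail("`prior_w` must be a single positive number")
  }
  if (any(!is.finite(z_gwas))) fail("non-finite z_gwas")
  shrink <- prior_w / (1 + prior_w)
  0.5 * log(1 / (1 + prior_w)) + (z_gwas^2 / 2) * shrink
}

#' Greedy LD pruning of a gene's eSNPs
#'
#' Sorts by eQTL p ascending and keeps an eSNP iff its panel r-squared with
#' every already-kept eSNP is `<= r2_max`, preventing LD-duplicated signals
#' from inflating the gene score. eSNPs absent from the panel cannot be
#' checked and are kept with a warning.
#'
#' @param esnps data.frame `rsid, gene_id, p_eqtl` for one gene.
#' @param panel a `genotype_panel`.
#' @param r2_max maximum tolerated pairwise r-squared, in (0, 1].
#' @return the pruned subset of `esnps` in p-ascending order.
#' @export
prune_esnps_by_ld <- function(esnps, panel, r2_max = 0.8) {
  if (!is.numeric(r2_max) || r2_max <= 0 || r2_max > 1) {
    fail("`r2_max` must lie in (0, 1]")
  }
  if (nrow(esnps) <= 1L) return(esnps)
  d <- esnps[order(esnps$p_eqtl), , drop = FALSE]
  in_panel <- d$rsid %in% panel$snp_ids
  if (any(!in_panel)) {
    warning("eSNP(s) absent from panel kept unpruned: ",
            paste(d$rsid[!in_panel], collapse = ", "), call. = FALSE)
  }
  dos <- panel$dosage[, d$rsid[in_panel], drop = FALSE]
  R2 <- suppressWarnings(cor(dos))^2
  R2[!is.finite(R2)] <- 1  # monomorphic columns: treat as redundant

  keep <- logical(nrow(d))
  kept_panel <- integer(0)  # indices into the panel-backed columns
  panel_idx <- cumsum(in_panel)
  for (i in seq_len(nrow(d))) {
    if (!in_panel[i]) {
      keep[i] <- TRUE
      next
    }
    j <- panel_idx[i]
    keep[i] <- length(kept_panel) == 0 || all(R2[j, kept_panel] <= r2_max)
    if (keep[i]) kept_panel <- c(kept_panel, j)
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate pruned eSNP scores into a gene log Bayes factor
#'
#' The gene score is the exact sum of its retained eSNPs' log Bayes factors.
#' Genes without any eSNP receive no score and must not be passed here; the
#' pipeline simply omits them from its results.
#'
#' @param gene_id the gene.
#' @param scores data.frame of scored eSNPs for this gene, with columns
#'   `gene_id, rsid, p_eqtl, p_gwas, z_gwas, log_bf, scenario`.
#' @return one-row data.frame `gene_id, lbf, n_esnps`.
#' @export
gene_lbf <- function(gene_id, scores) {
  if (nrow(scores) == 0) fail("gene %s has no eSNP scores", gene_id)
  if (!all(scores$gene_id == gene_id)) {
    fail("scores for gene %s contain other gene ids: %s", gene_id,
         paste(setdiff(unique(scores$gene_id), gene_id), collapse = ", "))
  }
  data.frame(gene_id = gene_id, lbf = sum(scores$log_bf),
             n_esnps = nrow(scores), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector, each in (0, 1].
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1)) {
    fail("p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

# score eSNPs of all genes against the GWAS and LD-prune per gene
score_esnps <- function(esnps, gwas, panel, prior_w, r2_max) {
  idx <- match(esnps$rsid, gwas$rsid)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " eSNP(s) absent from the GWAS were dropped",
            call. = FALSE)
    esnps <- esnps[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  esnps$p_gwas <- gwas$pvalue[idx]
  esnps$z_gwas <- p_to_z(esnps$p_gwas)

  pruned <- lapply(split(esnps, esnps$gene_id), function(g) {
    prune_esnps_by_ld(g, panel, r2_max)
  })
  scored <- do.call(rbind, c(pruned, list(make.row.names = FALSE)))
  scored$log_bf <- snp_log_bayes_factor(scored$z_gwas, prior_w)
  scored$scenario <- ifelse(scored$log_bf > 0, "positive", "negative")
  scored[c("gene_id", "rsid", "p_eqtl", "p_gwas", "z_gwas", "log_bf", "scenario")]
}

#' Attach permutation-based simulated p-values to gene LBF results
#'
#' For each of `B` replicates the genome-wide pool of GWAS z-scores is
#' reassigned to SNPs by a uniform random permutation while the eSNP
#' structure stays fixed, and every gene's LBF is recomputed. The simulated
#' p-value is `(1 + #[null lbf >= observed]) / (B + 1)`, so its floor is
#' `1/(B+1)` and it can never be exactly 0.
#'
#' @param results gene LBF data.frame from [run_bayes()] machinery, carrying
#'   a `contributions` attribute (per-eSNP scores).
#' @param gwas the GWAS table supplying the z pool.
#' @param B number of null replicates (>= 100; smaller tails are unstable).
#' @param seed permutation seed.
#' @param prior_w prior variance used for the observed scores.
#' @return `results` with `simulated_p` filled.
#' @export
simulated_gene_pvalues <- function(results, gwas, B = 1000L, seed = 1L,
                                   prior_w = 0.1) {
  if (B < 100L) fail("`B` must be >= 100 (unstable tail below that)")
  contrib <- attr(results, "contributions")
  if (is.null(contrib)) fail("`results` lacks the contributions attribute")
  set.seed(stage_seed(seed, "simulated-p"))

  z_pool <- abs(gwas$beta / gwas$se)
  n <- length(z_pool)
  snp_idx <- match(contrib$rsid, gwas$rsid)
  gene_f <- factor(contrib$gene_id)
  observed <- results$lbf
  # rowsum orders rows by factor level; map back to the results order by name
  row_of <- match(results$gene_id, levels(gene_f))
  if (anyNA(row_of)) fail("contributions do not cover every result gene")

  count_ge <- numeric(nrow(results))
  for (b in seq_len(B)) {
    zp <- z_pool[sample.int(n)]
    lbf_b <- rowsum(snp_log_bayes_factor(zp[snp_idx], prior_w), gene_f)[row_of, 1]
    count_ge <- count_ge + (lbf_b >= observed - 1e-12)
  }
  results$simulated_p <- (1 + count_ge) / (B + 1)
  results
}

#' Run the full Bayesian GWAS-eQTL integration for one eQTL dataset
#'
#' eSNP discovery, LD pruning, Wakefield scoring, gene LBF aggregation,
#' permutation simulated p-values and Benjamini-Hochberg adjustment, in one
#' call. Genes without eSNPs are absent from the result (the unscored
#' scenario).
#'
#' @param gwas GWAS summary data.frame.
#' @param eqtl eQTL association data.frame.
#' @param panel reference `genotype_panel` for LD pruning.
#' @param esnp_p eSNP threshold (inclusive).
#' @param prior_w Wakefield prior variance.
#' @param r2_max LD pruning threshold.
#' @param B simulated-p replicates.
#' @param seed permutation seed.
#' @return data.frame `gene_id, lbf, n_esnps, simulated_p, bh_q`, sorted by
#'   `simulated_p` then decreasing `lbf`, with per-eSNP scores in the
#'   `contributions` attribute.
#' @export
run_bayes <- function(gwas, eqtl, panel, esnp_p = 1e-4, prior_w = 0.1,
                      r2_max = 0.8, B = 1000L, seed = 1L) {
  esnps <- identify_esnps(eqtl, esnp_p)
  if (nrow(esnps) == 0) {
    out <- data.frame(gene_id = character(0), lbf = numeric(0),
                      n_esnps = integer(0), simulated_p = numeric(0),
                      bh_q = numeric(0), stringsAsFactors = FALSE)
    attr(out, "contributions") <- data.frame()
    return(out)
  }
  scored <- score_esnps(esnps, gwas, panel, prior_w, r2_max)
  results <- do.call(rbind, c(
    lapply(split(scored, scored$gene_id), function(g) gene_lbf(g$gene_id[1], g)),
    list(make.row.names = FALSE)
  ))
  attr(results, "contributions") <- scored
  results <- simulated_gene_pvalues(results, gwas, B = B, seed = seed,
                                    prior_w = prior_w)
  results$bh_q <- bh_adjust(results$simulated_p)
  results <- results[order(results$simulated_p, -results$lbf), , drop = FALSE]
  rownames(results) <- NULL
  attr(results, "contributions") <- scored
  results
}
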