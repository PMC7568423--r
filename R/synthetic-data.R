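#' Simulation configuration for the synthetic study
#'
#' Builds the parameter list consumed by [make_truth()]. Defaults mirror the
#' study conditions the pipeline is designed for: a moderate-to-severe asthma
#' GWAS of 30,810 subjects integrated with a monocyte eQTL panel of 1,490
#' subjects, and bronchial-epithelium expression groups of 44 severe / 72
#' mild-moderate / 38 control samples. Planted colocalized genes carry a
#' noncentrality of 6 on both the GWAS and eQTL sides (`effect = ncp/sqrt(n)`),
#' i.e. clearly detectable but not overwhelming signals.
#'
#' @param n_genes number of genes in the simulated universe.
#' @param snps_per_gene SNPs simulated per gene locus; together with
#'   `n_genes` this fixes the SNP count.
#' @param n_planted number of truly colocalized genes (eQTL and GWAS signal
#'   at the same SNPs).
#' @param gwas_ncp,eqtl_ncp planted noncentrality `sqrt(n) * effect` on the
#'   GWAS and eQTL z scale.
#' @param n_gwas,n_eqtl GWAS and eQTL sample sizes.
#' @param ld_decay adjacent-SNP latent AR(1) correlation within an LD block,
#'   in `[0, 1)`.
#' @param block_size SNPs per LD block (blocks never straddle gene loci).
#' @param n_samples_panel samples in the reference genotype panel.
#' @param maf_range range of simulated minor-allele frequencies; default
#'   mirrors the conventional MAF >= 5% filter of array eQTL studies.
#' @param n_deg genes with a planted group-wise expression shift.
#' @param deg_shift mean expression shift (in noise-sd units when
#'   `noise_sd = 1`) added to `deg_genes` in `deg_groups`.
#' @param noise_sd residual sd of simulated expression.
#' @param groups named integer vector of expression group sizes.
#' @param deg_groups group labels receiving the planted shift.
#' @param trans_genes gene ids additionally given one trans eSNP each in
#'   simulated eQTL data.
#' @param gene_spacing,snp_spacing base-pair spacing between gene loci and
#'   between SNPs within a locus.
#' @return a named list of validated simulation parameters.
#' @export
sim_config <- function(n_genes = 1000L, snps_per_gene = 5L, n_planted = 20L,
                       gwas_ncp = 6, eqtl_ncp = 6,
                       n_gwas = 30810L, n_eqtl = 1490L,
                       ld_decay = 0.5, block_size = snps_per_gene,
                       n_samples_panel = 500L,
                       maf_range = c(0.05, 0.5),
                       n_deg = 0L, deg_shift = 0, noise_sd = 1,
                       groups = c(SA = 44L, notSA = 72L, Control = 38L),
                       deg_groups = "SA",
                       trans_genes = character(0),
                       gene_spacing = 2e6, snp_spacing = 1000) {
  cfg <- list(
    n_genes = as.integer(n_genes), snps_per_gene = as.integer(snps_per_gene),
    n_planted = as.integer(n_planted),
    gwas_ncp = gwas_ncp, eqtl_ncp = eqtl_ncp,
    n_gwas = as.integer(n_gwas), n_eqtl = as.integer(n_eqtl),
    gwas_effect = gwas_ncp / sqrt(n_gwas),
    eqtl_effect = eqtl_ncp / sqrt(n_eqtl),
    ld_decay = ld_decay, block_size = as.integer(block_size),
    n_samples_panel = as.integer(n_samples_panel),
    maf_range = maf_range,
    n_deg = as.integer(n_deg), deg_shift = deg_shift, noise_sd = noise_sd,
    groups = groups, deg_groups = deg_groups, trans_genes = trans_genes,
    gene_spacing = gene_spacing, snp_spacing = snp_spacing
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  for (f in c("n_genes", "snps_per_gene", "n_samples_panel", "n_gwas",
              "n_eqtl", "block_size")) {
    if (cfg[[f]] < 1L) fail("config field `%s` must be >= 1 (got %d)", f, cfg[[f]])
  }
  if (cfg$n_planted < 0L || cfg$n_planted > cfg$n_genes) {
    fail("config field `n_planted` (%d) must lie in [0, n_genes = %d]",
         cfg$n_planted, cfg$n_genes)
  }
  if (cfg$n_deg < 0L || cfg$n_deg > cfg$n_genes) {
    fail("config field `n_deg` (%d) must lie in [0, n_genes = %d]",
         cfg$n_deg, cfg$n_genes)
  }
  if (cfg$ld_decay < 0 || cfg$ld_decay >= 1) {
    fail("config field `ld_decay` must lie in [0, 1) (got %g)", cfg$ld_decay)
  }
  invisible(cfg)
}

#' Resolve the ground truth of a synthetic study
#'
#' Draws the planted colocalized genes, planted differential-expression
#' genes, per-SNP allele frequencies, and the full SNP/gene map from a
#' configuration and a seed. The returned object is the single source from
#' which [simulate_ld_panel()], [simulate_gwas()], [simulate_eqtl()] and
#' [simulate_expression()] generate data: identical `(config, seed)` pairs
#' reproduce identical outputs everywhere downstream.
#'
#' Gene loci are laid out on chromosomes 1-22 with a `gene_spacing` gap so
#' that annotation windows never leak across loci; each locus carries
#' `snps_per_gene` SNPs at `snp_spacing` intervals, partitioned into LD
#' blocks of `block_size`.
#'
#' @param config a list from [sim_config()].
#' @param seed integer seed.
#' @return an object of class `sim_truth` with elements `config`, `seed`,
#'   `genes` (gene models, 1-based inclusive), `snps` (SNP map with gene,
#'   block and allele frequency), `planted_genes`, `planted_snps`,
#'   `deg_genes`.
#' @export
make_truth <- function(config = sim_config(), seed = 1L) {
  validate_sim_config(config)
  n_genes <- config$n_genes
  spg <- config$snps_per_gene
  n_snps <- n_genes * spg

  gene_id <- sprintf("G%04d", seq_len(n_genes))
  chrom <- paste0("chr", ((seq_len(n_genes) - 1L) %% 22L) + 1L)
  idx_on_chrom <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
  start <- (idx_on_chrom - 1L) * config$gene_spacing + 100000
  end <- start + (spg - 1L) * config$snp_spacing
  genes <- data.frame(gene_id = gene_id, chrom = chrom,
                      start = start, end = end, stringsAsFactors = FALSE)

  snp_gene <- rep(gene_id, each = spg)
  within <- rep(seq_len(spg), times = n_genes)
  snps <- data.frame(
    rsid = sprintf("rs%06d", seq_len(n_snps)),
    chrom = rep(chrom, each = spg),
    pos = rep(start, each = spg) + (within - 1L) * config$snp_spacing,
    gene_id = snp_gene,
    block = paste0(snp_gene, "_b", (within - 1L) %/% config$block_size + 1L),
    stringsAsFactors = FALSE
  )

  set.seed(stage_seed(seed, "truth"))
  planted_genes <- sort(sample(gene_id, config$n_planted))
  deg_genes <- sort(sample(gene_id, config$n_deg))
  snps$maf <- runif(n_snps, config$maf_range[1], config$maf_range[2])

  # one causal SNP per planted gene: the central SNP of the locus
  mid <- (spg + 1L) %/% 2L
  planted_snps <- data.frame(
    gene_id = planted_genes,
    rsid = snps$rsid[match(planted_genes, snps$gene_id) + (mid - 1L)],
    stringsAsFactors = FALSE
  )

  structure(
    list(config = config, seed = as.integer(seed), genes = genes, snps = snps,
         planted_genes = planted_genes, planted_snps = planted_snps,
         deg_genes = deg_genes),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "sim_truth: %d genes x %d SNPs (%d planted colocalized, %d DEG), seed %d\n",
    x$config$n_genes, nrow(x$snps), length(x$planted_genes),
    length(x$deg_genes), x$seed))
  invisible(x)
}

#' Simulate an LD-structured reference genotype panel
#'
#' Dosages are generated per LD block from a latent Gaussian AR(1) process
#' with adjacent-SNP correlation `ld_decay`, thresholded to \{0, 1, 2\} at the
#' Hardy-Weinberg quantiles of each SNP's allele frequency. SNPs in different
#' blocks are independent; `ld_decay = 0` gives a fully independent panel.
#'
#' @param truth a `sim_truth` object.
#' @return an object of class `genotype_panel`: list with `sample_ids`,
#'   `snp_ids` (in SNP-map order) and the `dosage` matrix (samples x SNPs,
#'   entries in 0..2, no missingness).
#' @export
simulate_ld_panel <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  cfg <- truth$config
  n <- cfg$n_samples_panel
  rho <- cfg$ld_decay
  set.seed(stage_seed(truth$seed, "panel"))

  n_snps <- nrow(truth$snps)
  latent <- matrix(rnorm(n * n_snps), nrow = n)
  # sequential AR(1) within each block; block boundaries reset the chain
  blk <- truth$snps$block
  if (rho > 0) {
    same_block <- c(FALSE, blk[-1L] == blk[-n_snps])
    scale <- sqrt(1 - rho^2)
    for (j in seq_len(n_snps)[-1L]) {
      if (same_block[j]) {
        latent[, j] <- rho * latent[, j - 1L] + scale * latent[, j]
      }
    }
  }
  f <- truth$snps$maf
  lo <- qnorm((1 - f)^2)   # below: 0 copies of the alternate allele
  hi <- qnorm(1 - f^2)     # above: 2 copies
  dosage <- sweep(latent, 2L, lo, ">") + sweep(latent, 2L, hi, ">")
  storage.mode(dosage) <- "double"
  dimnames(dosage) <- list(sprintf("S%04d", seq_len(n)), truth$snps$rsid)

  structure(list(sample_ids = rownames(dosage), snp_ids = colnames(dosage),
                 dosage = dosage),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d SNPs\n",
              length(x$sample_ids), length(x$snp_ids)))
  invisible(x)
}

# block correlation with optional ridge when numerically non-PD
block_cor <- function(dos, ridge_eps = 1e-6) {
  R <- suppressWarnings(cor(dos))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    warning("near-singular block correlation; ridge-regularized with eps = ",
            ridge_eps, call. = FALSE)
    m <- nrow(R)
    R <- (R + diag(ridge_eps, m)) / (1 + ridge_eps)
  }
  R
}

#' Simulate GWAS summary statistics with planted associations
#'
#' Per LD block, z-scores are drawn from a multivariate normal with
#' covariance `R` (the block's dosage correlation estimated from the panel)
#' and mean `R %*% lambda0`, where `lambda0` is nonzero only at planted SNPs
#' and equals `sqrt(n_gwas) * gwas_effect` there — the standard propagation
#' of a causal signal through LD. Effects live directly on the z scale, so
#' `beta` is reported as z and `se` as 1; this matches a pipeline that only
#' ever consumes summary statistics.
#'
#' @param truth a `sim_truth`.
#' @param panel the `genotype_panel` generated from the same truth.
#' @return a GWAS summary data.frame (columns `rsid, chrom, pos, ea, oa,
#'   beta, se, pvalue, n`), one row per SNP.
#' @export
simulate_gwas <- function(truth, panel) {
  stopifnot(inherits(truth, "sim_truth"), inherits(panel, "genotype_panel"))
  cfg <- truth$config
  set.seed(stage_seed(truth$seed, "gwas"))

  n_snps <- nrow(truth$snps)
  lambda0 <- numeric(n_snps)
  lambda0[match(truth$planted_snps$rsid, truth$snps$rsid)] <-
    sqrt(cfg$n_gwas) * cfg$gwas_effect

  z <- numeric(n_snps)
  for (idx in split(seq_len(n_snps), truth$snps$block)) {
    m <- length(idx)
    if (m == 1L) {
      z[idx] <- lambda0[idx] + rnorm(1L)
    } else {
      R <- block_cor(panel$dosage[, idx, drop = FALSE])
      mu <- drop(R %*% lambda0[idx])
      z[idx] <- mu + drop(crossprod(chol(R), rnorm(m)))
    }
  }

  data.frame(
    rsid = truth$snps$rsid, chrom = truth$snps$chrom, pos = truth$snps$pos,
    ea = "A", oa = "G", beta = z, se = 1, pvalue = z_to_p(z),
    n = cfg$n_gwas, stringsAsFactors = FALSE
  )
}

#' Simulate one eQTL association dataset
#'
#' Every gene is paired with its cis SNPs (the SNPs of its locus). For
#' planted colocalized genes those pairs receive eQTL z-scores centred at
#' `sqrt(n_eqtl) * eqtl_effect`; all other pairs are null. Genes listed in
#' `config$trans_genes` additionally get one trans eSNP drawn from a distant
#' locus. Different `dataset_label`s share the (SNP, gene) skeleton and the
#' planted signal but redraw the noise independently, emulating independent
#' eQTL studies of the same biology.
#'
#' @param truth a `sim_truth`.
#' @param panel unused; accepted for interface symmetry with the other
#'   simulators (eQTL z-scores are drawn marginally).
#' @param dataset_label label distinguishing independent datasets.
#' @param seed base seed; defaults to the truth's seed. The label is folded
#'   into the stream so labels differ deterministically.
#' @return an eQTL data.frame (`rsid, gene_id, pvalue, beta, dataset_label,
#'   cis_trans`).
#' @export
simulate_eqtl <- function(truth, panel = NULL, dataset_label = "eqtl1",
                          seed = truth$seed) {
  stopifnot(inherits(truth, "sim_truth"))
  cfg <- truth$config
  set.seed(stage_seed(seed, paste0("eqtl:", dataset_label)))

  pairs <- data.frame(
    rsid = truth$snps$rsid, gene_id = truth$snps$gene_id,
    cis_trans = "cis", stringsAsFactors = FALSE
  )
  if (length(cfg$trans_genes) > 0) {
    tg <- intersect(cfg$trans_genes, truth$genes$gene_id)
    # deterministic distant partner: the locus half a genome away
    gi <- match(tg, truth$genes$gene_id)
    partner <- ((gi - 1L + cfg$n_genes %/% 2L) %% cfg$n_genes) + 1L
    trans_rsid <- truth$snps$rsid[(partner - 1L) * cfg$snps_per_gene + 1L]
    pairs <- rbind(pairs, data.frame(rsid = trans_rsid, gene_id = tg,
                                     cis_trans = "trans",
                                     stringsAsFactors = FALSE))
  }

  ncp <- sqrt(cfg$n_eqtl) * cfg$eqtl_effect
  mu <- ifelse(pairs$gene_id %in% truth$planted_genes, ncp, 0)
  # trans pairs of planted genes also carry signal; of unplanted genes, null
  z <- mu + rnorm(nrow(pairs))
  data.frame(
    rsid = pairs$rsid, gene_id = pairs$gene_id,
    pvalue = z_to_p(z), beta = z / sqrt(cfg$n_eqtl),
    dataset_label = dataset_label, cis_trans = pairs$cis_trans,
    stringsAsFactors = FALSE
  )
}

#' Simulate a grouped expression matrix
#'
#' Gaussian noise around zero for every gene; planted DEG genes get
#' `deg_shift` added in the samples of `deg_groups`. Group sizes default to
#' the configured severe / mild-moderate / control design.
#'
#' @param truth a `sim_truth`.
#' @param groups named integer vector of group sizes (>= 2 groups, each of
#'   size >= 2).
#' @param seed seed for the expression noise.
#' @return an `expression_matrix` object: list with `expr` (genes x samples)
#'   and `meta` (`sample_id`, `group`).
#' @export
simulate_expression <- function(truth, groups = truth$config$groups,
                                seed = truth$seed) {
  stopifnot(inherits(truth, "sim_truth"))
  cfg <- truth$config
  if (length(groups) < 2L) fail("`groups` must contain at least 2 groups")
  if (any(groups < 2L)) {
    fail("every group needs >= 2 samples (got: %s)",
         paste(sprintf("%s=%d", names(groups), groups), collapse = ", "))
  }
  set.seed(stage_seed(seed, "expression"))

  n_samples <- sum(groups)
  group <- rep(names(groups), times = groups)
  sample_id <- sprintf("%s_%02d", group,
                       unlist(lapply(groups, seq_len), use.names = FALSE))
  expr <- matrix(rnorm(cfg$n_genes * n_samples, sd = cfg$noise_sd),
                 nrow = cfg$n_genes,
                 dimnames = list(truth$genes$gene_id, sample_id))
  if (length(truth$deg_genes) > 0 && cfg$deg_shift != 0) {
    shifted_cols <- group %in% cfg$deg_groups
    expr[truth$deg_genes, shifted_cols] <-
      expr[truth$deg_genes, shifted_cols] + cfg$deg_shift
  }
  new_expression_matrix(expr, data.frame(sample_id = sample_id, group = group,
                                         stringsAsFactors = FALSE))
}

new_expression_matrix <- function(expr, meta) {
  if (anyDuplicated(rownames(expr))) fail("duplicate gene ids in expression matrix")
  if (!all(colnames(expr) %in% meta$sample_id)) {
    fail("every expression sample needs a metadata row")
  }
  structure(list(expr = expr, meta = meta), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x$expr), ncol(x$expr),
              paste(sprintf("%s=%d", names(table(x$meta$group)),
                            as.integer(table(x$meta$group))), collapse = ", ")))
  invisible(x)
}
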