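# End-to-end orchestration on synthetic data: simulate -> Bayesian
# integration per eQTL dataset -> gene-based test -> negative-control GWAS ->
# consensus, with optional run-directory output.

#' Run the full prioritization pipeline on synthetic data
#'
#' Generates a study from `(config, seed)`, runs the Bayesian integration
#' once per eQTL dataset label, the LD-aware gene-based test on the GWAS,
#' the gene-based test on a random-phenotype negative-control GWAS, and the
#' consensus filter across all real analyses.
#'
#' @param config simulation configuration from [sim_config()].
#' @param seed master seed; every stage derives its stream from it.
#' @param eqtl_labels labels of the independent eQTL datasets to simulate
#'   and integrate.
#' @param esnp_p,prior_w,r2_max,B parameters of [run_bayes()].
#' @param window_bp gene-based assignment window.
#' @param alpha consensus inclusion threshold.
#' @param n_cases cases for the negative-control GWAS (default: half the
#'   panel).
#' @param catalog optional documented-gene list for the consensus flag.
#' @param out_dir optional directory; when given, all inputs and outputs are
#'   written there (TSV/BED/CSV/JSON) together with a small run manifest.
#' @return list with `truth`, `panel`, `gwas`, `eqtl` (list), `bayes`
#'   (list of per-dataset results), `gene_based`, `null_snp` (per-SNP null
#'   GWAS), `null_gene` (gene-based on the null GWAS), `consensus`, `venn`.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1L,
                         eqtl_labels = c("eqtl1", "eqtl2", "eqtl3"),
                         esnp_p = 1e-4, prior_w = 0.1, r2_max = 0.8,
                         B = 500L, window_bp = 20000L, alpha = 0.05,
                         n_cases = NULL, catalog = NULL, out_dir = NULL) {
  truth <- make_truth(config, seed)
  panel <- simulate_ld_panel(truth)
  gwas <- simulate_gwas(truth, panel)
  eqtl <- lapply(eqtl_labels, function(lbl) {
    simulate_eqtl(truth, panel, dataset_label = lbl, seed = seed)
  })
  names(eqtl) <- eqtl_labels

  bayes <- lapply(eqtl, function(e) {
    run_bayes(gwas, e, panel, esnp_p = esnp_p, prior_w = prior_w,
              r2_max = r2_max, B = B, seed = seed)
  })
  gene_based <- run_gene_based(gwas, truth$genes, panel, window_bp = window_bp)

  if (is.null(n_cases)) n_cases <- length(panel$sample_ids) %/% 2L
  null_snp <- null_gwas(panel, n_cases = n_cases, seed = seed)
  null_gwas_tbl <- data.frame(
    rsid = null_snp$rsid, chrom = truth$snps$chrom, pos = truth$snps$pos,
    ea = "A", oa = "G", beta = sqrt(null_snp$chisq), se = 1,
    pvalue = null_snp$pvalue, n = length(panel$sample_ids),
    stringsAsFactors = FALSE)
  null_gene <- run_gene_based(null_gwas_tbl, truth$genes, panel,
                              window_bp = window_bp)

  results <- c(
    lapply(bayes, function(b) setNames(b$simulated_p, b$gene_id)),
    list(gene_based = setNames(gene_based$pvalue, gene_based$gene_id))
  )
  consensus <- build_consensus_table(
    results, alpha = alpha,
    null_control = setNames(null_gene$pvalue, null_gene$gene_id),
    catalog = catalog)
  venn <- intersect_results(lapply(results, function(m) names(m)[m < alpha]))

  out <- list(truth = truth, panel = panel, gwas = gwas, eqtl = eqtl,
              bayes = bayes, gene_based = gene_based, null_snp = null_snp,
              null_gene = null_gene, consensus = consensus, venn = venn)
  if (!is.null(out_dir)) write_run_dir(out, out_dir)
  out
}

write_run_dir <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_truth_json(run$truth, p("truth.json"))
  write_gene_bed(run$truth$genes, p("genes.bed"))
  write_gwas_tsv(run$gwas, p("gwas.tsv"))
  write_genotype_tsv(run$panel, p("panel.tsv"))
  for (lbl in names(run$eqtl)) {
    write_eqtl_tsv(run$eqtl[[lbl]], p(sprintf("eqtl_%s.tsv", lbl)))
  }
  for (lbl in names(run$bayes)) {
    b <- run$bayes[[lbl]]
    write.table(b, p(sprintf("bayes_%s.tsv", lbl)), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(attr(b, "contributions"),
                         p(sprintf("bayes_%s_esnps.json", lbl)),
                         digits = NA)
  }
  write.table(run$gene_based, p("gene_based.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(run$null_snp, p("null_gwas_snp.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(run$consensus, p("consensus.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(run$venn$venn_counts), p("venn_counts.json"),
                       auto_unbox = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("priogene")),
    seed = run$truth$seed,
    n_genes = run$truth$config$n_genes,
    n_snps = nrow(run$truth$snps),
    eqtl_datasets = names(run$eqtl),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' Score planted-gene recovery of a pipeline run
#'
#' Convenience evaluation against the simulation ground truth: how many
#' planted colocalized genes rank in the LBF top-`k` of the discovery
#' dataset, and the consensus table's recall of planted genes and rate of
#' non-planted contamination.
#'
#' @param run a [run_pipeline()] result.
#' @param k size of the LBF top list (default: number of planted genes).
#' @return list `top_k_planted`, `consensus_recall`,
#'   `consensus_nonplanted_rate`.
#' @export
evaluate_recovery <- function(run, k = length(run$truth$planted_genes)) {
  planted <- run$truth$planted_genes
  disc <- run$bayes[[1]]
  top <- head(disc$gene_id[order(-disc$lbf)], k)
  n_nonplanted <- run$truth$config$n_genes - length(planted)
  cons <- run$consensus$gene_id
  list(
    top_k_planted = sum(top %in% planted),
    consensus_recall = if (length(planted) > 0) {
      length(intersect(cons, planted)) / length(planted)
    } else NA_real_,
    consensus_nonplanted_rate = length(setdiff(cons, planted)) / n_nonplanted
  )
}
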