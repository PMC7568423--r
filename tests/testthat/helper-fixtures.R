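# Shared small fixtures, built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small planted study: 50 genes x 5 SNPs, 5 colocalized
small_config <- function(...) {
  sim_config(n_genes = 50L, snps_per_gene = 5L, n_planted = 5L,
             n_samples_panel = 300L, ...)
}

small_study <- function(seed = 7L, config = small_config()) {
  truth <- make_truth(config, seed)
  panel <- simulate_ld_panel(truth)
  list(truth = truth, panel = panel,
       gwas = simulate_gwas(truth, panel),
       eqtl = simulate_eqtl(truth, panel, "eqtlA", seed = seed))
}

# hand-built panel from an explicit dosage matrix
panel_from_matrix <- function(m) {
  if (is.null(colnames(m))) colnames(m) <- sprintf("rs%03d", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%03d", seq_len(nrow(m)))
  structure(list(sample_ids = rownames(m), snp_ids = colnames(m), dosage = m),
            class = "genotype_panel")
}

# expression_matrix from an explicit matrix and group vector
em_from_matrix <- function(expr, group) {
  if (is.null(colnames(expr))) {
    colnames(expr) <- sprintf("s%02d", seq_len(ncol(expr)))
  }
  if (is.null(rownames(expr))) {
    rownames(expr) <- sprintf("g%02d", seq_len(nrow(expr)))
  }
  priogene:::new_expression_matrix(
    expr, data.frame(sample_id = colnames(expr), group = group,
                     stringsAsFactors = FALSE))
}

# oracle: correlation of two HWE-thresholded latent-bivariate-normal dosages,
# by brute-force 2D grid integration of the latent density
oracle_threshold_cor <- function(rho, f1, f2, lim = 6, step = 0.02) {
  z <- seq(-lim, lim, by = step)
  thresholds <- function(f) c(qnorm((1 - f)^2), qnorm(1 - f^2))
  dose <- function(zv, th) (zv > th[1]) + (zv > th[2])
  d1 <- dose(z, thresholds(f1))
  d2 <- dose(z, thresholds(f2))
  # bivariate normal density on the grid
  dens <- outer(z, z, function(a, b) {
    exp(-(a^2 - 2 * rho * a * b + b^2) / (2 * (1 - rho^2))) /
      (2 * pi * sqrt(1 - rho^2))
  })
  exy <- sum(outer(d1, d2) * dens) * step^2
  (exy - 4 * f1 * f2) / sqrt(2 * f1 * (1 - f1) * 2 * f2 * (1 - f2))
}
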