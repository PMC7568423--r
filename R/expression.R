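# Differential-expression and co-expression validation of candidate genes
# across labelled sample groups.

expr_vector <- function(em, gene_id) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!gene_id %in% rownames(em$expr)) fail("gene `%s` not in matrix", gene_id)
  em$expr[gene_id, em$meta$sample_id]
}

#' One-way ANOVA with Tukey HSD post hoc for one gene
#'
#' Fixed-effects one-way ANOVA of a gene's expression across the sample
#' groups, with Tukey honest-significant-difference adjusted pairwise
#' p-values from the studentized-range distribution (Tukey-Kramer form for
#' unequal group sizes, via [stats::TukeyHSD()]). With exactly two groups the
#' ANOVA p equals the pooled-variance two-sided t-test p (F = t^2), which is
#' also reported as `ttest_p`. Genes with zero within-group variance in
#' every group are flagged and carry an undefined p.
#'
#' @param em an `expression_matrix`.
#' @param gene_id the gene to test.
#' @return a `deg_result` list: `gene_id, group_means, f_stat, anova_p,
#'   tukey` (named vector of adjusted pairwise p), `ttest_p` (two-group runs
#'   only, else `NA`), `degenerate` flag.
#' @export
anova_tukey <- function(em, gene_id) {
  y <- expr_vector(em, gene_id)
  group <- factor(em$meta$group)
  if (nlevels(group) < 2L) fail("need at least 2 groups")
  if (any(table(group) < 2L)) fail("every group needs >= 2 samples")

  group_means <- tapply(y, group, mean)
  within_var <- tapply(y, group, stats::var)
  if (all(within_var == 0)) {
    return(structure(list(gene_id = gene_id, group_means = group_means,
                          f_stat = NA_real_, anova_p = NA_real_,
                          tukey = NULL, ttest_p = NA_real_, degenerate = TRUE),
                     class = "deg_result"))
  }
  fit <- aov(y ~ group)
  tab <- summary(fit)[[1]]
  tukey <- TukeyHSD(fit)$group[, "p adj"]
  ttest_p <- if (nlevels(group) == 2L) {
    two_group_ttest(em, gene_id, levels(group)[1], levels(group)[2])
  } else {
    NA_real_
  }
  structure(
    list(gene_id = gene_id, group_means = group_means,
         f_stat = tab[["F value"]][1], anova_p = tab[["Pr(>F)"]][1],
         tukey = tukey, ttest_p = ttest_p, degenerate = FALSE),
    class = "deg_result"
  )
}

#' @export
print.deg_result <- function(x, ...) {
  cat(sprintf("deg_result %s: F = %.4g, ANOVA p = %.4g\n",
              x$gene_id, x$f_stat, x$anova_p))
  invisible(x)
}

#' ANOVA over many genes
#'
#' Convenience wrapper running [anova_tukey()] per gene and collecting a flat
#' table; `tukey = FALSE` skips the post hoc for large calibration runs.
#'
#' @param em an `expression_matrix`.
#' @param genes genes to test (default: all).
#' @param tukey compute Tukey HSD per gene.
#' @return data.frame `gene_id, f_stat, anova_p` (plus a `tukey` list-column
#'   when requested).
#' @export
deg_table <- function(em, genes = rownames(em$expr), tukey = FALSE) {
  group <- factor(em$meta$group)
  x <- em$expr[genes, em$meta$sample_id, drop = FALSE]
  # vectorized one-way ANOVA: between/within decomposition per row
  n <- ncol(x)
  k <- nlevels(group)
  counts <- as.integer(table(group))
  gm <- rowMeans(x)
  group_sums <- x %*% stats::model.matrix(~ group - 1)
  group_means <- sweep(group_sums, 2L, counts, "/")
  ss_between <- drop((group_means - gm)^2 %*% counts)
  ss_total <- rowSums((x - gm)^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  f_stat <- (ss_between / (k - 1)) / (ss_within / (n - k))
  anova_p <- stats::pf(f_stat, k - 1, n - k, lower.tail = FALSE)
  out <- data.frame(gene_id = genes, f_stat = f_stat, anova_p = anova_p,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (tukey) {
    out$tukey <- lapply(genes, function(g) anova_tukey(em, g)$tukey)
  }
  out
}

#' Two-group Student's t-test for one gene
#'
#' Classical pooled-variance Student's t (two-sided); `welch = TRUE` switches
#' to the Welch unequal-variance form.
#'
#' @param em an `expression_matrix`.
#' @param gene_id the gene.
#' @param group_a,group_b group labels to compare.
#' @param welch use Welch's correction instead of the pooled variance.
#' @return the two-sided p-value.
#' @export
two_group_ttest <- function(em, gene_id, group_a, group_b, welch = FALSE) {
  y <- expr_vector(em, gene_id)
  group <- em$meta$group
  for (g in c(group_a, group_b)) {
    if (!g %in% group) fail("unknown group label `%s`", g)
  }
  ya <- y[group == group_a]
  yb <- y[group == group_b]
  if (length(ya) < 2L || length(yb) < 2L) fail("both groups need >= 2 samples")
  if (stats::var(ya) == 0 && stats::var(yb) == 0 && mean(ya) == mean(yb)) {
    return(1)  # identical constant groups: no evidence at all
  }
  t.test(ya, yb, var.equal = !welch)$p.value
}

#' Within-group co-expression matrix
#'
#' Pearson correlations among the requested genes computed over one group's
#' samples only. Constant genes have undefined correlations; their entries
#' are `NA` and reported through a warning.
#'
#' @param em an `expression_matrix`.
#' @param genes genes to correlate.
#' @param group group label (needs >= 3 samples).
#' @return a `coexpression_matrix` object: list with `cor` (gene x gene),
#'   `group`, `n_samples`.
#' @export
coexpression_matrix <- function(em, genes, group) {
  stopifnot(inherits(em, "expression_matrix"))
  missing <- setdiff(genes, rownames(em$expr))
  if (length(missing) > 0) {
    fail("gene(s) not in matrix: %s", paste(missing, collapse = ", "))
  }
  samples <- em$meta$sample_id[em$meta$group == group]
  if (length(samples) < 3L) {
    fail("group `%s` has %d sample(s); need >= 3", group, length(samples))
  }
  x <- t(em$expr[genes, samples, drop = FALSE])
  constant <- apply(x, 2L, stats::sd) == 0
  if (any(constant)) {
    warning("constant gene(s) in group ", group, ": ",
            paste(genes[constant], collapse = ", "), call. = FALSE)
  }
  cc <- suppressWarnings(cor(x))
  diag(cc) <- 1
  structure(list(cor = cc, group = group, n_samples = length(samples)),
            class = "coexpression_matrix")
}

#' @export
print.coexpression_matrix <- function(x, ...) {
  cat(sprintf("coexpression_matrix: %d genes, group %s (n = %d)\n",
              nrow(x$cor), x$group, x$n_samples))
  invisible(x)
}
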