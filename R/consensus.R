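# Cross-analysis consensus: intersection / Venn counts of significant gene
# sets, the consensus table with negative-control and catalog annotation.

#' Intersect named gene sets and tally Venn regions
#'
#' Computes the intersection across all sets; for up to 4 sets also returns
#' exclusive Venn region counts keyed by the sorted combination of set labels
#' (e.g. `"A&B"`), which sum to the size of the union. With more than 4 sets
#' the intersection is still computed but Venn counts are refused.
#'
#' @param sets named list (>= 2) of gene-id vectors.
#' @return list with `intersection` (sorted gene ids) and `venn_counts`
#'   (named integer vector, or `NULL` with a warning for > 4 sets).
#' @export
intersect_results <- function(sets) {
  if (length(sets) < 2L) fail("need at least 2 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    fail("sets must be named")
  }
  sets <- lapply(sets, unique)
  intersection <- sort(Reduce(intersect, sets))

  venn_counts <- NULL
  if (length(sets) <= 4L) {
    universe <- unique(unlist(sets))
    membership <- vapply(sets, function(s) universe %in% s,
                         logical(length(universe)))
    if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
    region <- apply(membership, 1L, function(m) {
      paste(names(sets)[m], collapse = "&")
    })
    venn_counts <- table(region)
    venn_counts <- setNames(as.integer(venn_counts), names(venn_counts))
  } else {
    warning("Venn counts refused for more than 4 sets", call. = FALSE)
  }
  list(intersection = intersection, venn_counts = venn_counts)
}

as_p_map <- function(x, what) {
  if (is.data.frame(x)) {
    pcol <- intersect(c("simulated_p", "pvalue", "p"), names(x))[1]
    if (is.na(pcol) || !"gene_id" %in% names(x)) {
      fail("%s must have gene_id and a p-value column", what)
    }
    setNames(x[[pcol]], x$gene_id)
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    fail("%s must be a data.frame or a named numeric vector", what)
  }
}

#' Build the cross-analysis consensus table
#'
#' A gene enters the table iff its p-value is below `alpha` in *every* real
#' analysis (genes missing from an analysis are not significant there). The
#' negative-control p and the catalog flag are attached for reporting but
#' never filtered on. Rows are sorted by the first (discovery) analysis' p.
#'
#' @param results named list of per-analysis gene->p maps (data.frames with
#'   `gene_id` and `simulated_p`/`pvalue`, or named numeric vectors). The
#'   first entry is the discovery analysis.
#' @param alpha per-analysis inclusion threshold (default 0.05, uncorrected,
#'   the operational choice of the consensus design; corrected q-values are
#'   carried in the per-stage outputs instead).
#' @param null_control optional gene->p map from the random-phenotype
#'   negative control.
#' @param catalog optional vector of documented (catalog) gene ids.
#' @return data.frame with `gene_id`, one `p_<label>` column per analysis,
#'   `null_control_p`, `documented`.
#' @export
build_consensus_table <- function(results, alpha = 0.05, null_control = NULL,
                                  catalog = NULL) {
  if (length(results) < 1L) fail("need at least one analysis")
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    fail("`results` must be a named list")
  }
  if (alpha < 0 || alpha > 1) fail("`alpha` must lie in [0, 1]")
  maps <- lapply(seq_along(results), function(i) {
    as_p_map(results[[i]], sprintf("results[[%d]]", i))
  })
  names(maps) <- names(results)

  sig_sets <- lapply(maps, function(m) names(m)[m < alpha])
  consensus <- Reduce(intersect, sig_sets)
  if (length(consensus) == 0) {
    out <- data.frame(gene_id = character(0), stringsAsFactors = FALSE)
    for (lbl in names(maps)) out[[paste0("p_", lbl)]] <- numeric(0)
    out$null_control_p <- numeric(0)
    out$documented <- logical(0)
    return(out)
  }
  out <- data.frame(gene_id = consensus, stringsAsFactors = FALSE)
  for (lbl in names(maps)) out[[paste0("p_", lbl)]] <- unname(maps[[lbl]][consensus])

  if (is.null(null_control)) {
    out$null_control_p <- NA_real_
  } else {
    ncm <- as_p_map(null_control, "null_control")
    missing <- setdiff(consensus, names(ncm))
    if (length(missing) > 0) {
      warning("gene(s) absent from the null control: ",
              paste(missing, collapse = ", "), call. = FALSE)
    }
    out$null_control_p <- unname(ncm[consensus])
  }
  out <- annotate_catalog(out, catalog)
  out <- out[order(out[[paste0("p_", names(maps)[1])]]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Published per-gene p-values of the moderate-to-severe asthma consensus
#'
#' The per-gene p-values printed by a published integrative analysis of
#' moderate-to-severe asthma for its 11 consensus genes: simulated p in the
#' discovery eQTL dataset and two replication eQTL datasets, the gene-based
#' GWAS p, the negative-control (random phenotype) gene-based p, and whether
#' the gene was already documented in the GWAS catalog. Bundled as a worked
#' example for [build_consensus_table()]: feeding these columns through the
#' consensus filter at `alpha = 0.05` reconstructs the published table.
#'
#' @return data.frame with columns `gene_id`, `sherlock_discovery_p`,
#'   `sherlock_rep1_p`, `sherlock_rep2_p`, `gene_based_p`, `null_control_p`,
#'   `documented` (logical).
#' @export
published_consensus_pvalues <- function() {
  path <- system.file("extdata", "moderate_severe_asthma_consensus_pvalues.tsv",
                      package = "priogene", mustWork = TRUE)
  d <- read.delim(path, stringsAsFactors = FALSE)
  d$documented <- d$documented == "yes"
  d
}

#' Flag consensus genes documented in a supplied catalog
#'
#' Stand-in for a live disease-catalog lookup: `documented = gene %in%
#' catalog`. Without a catalog every row is flagged not-documented.
#'
#' @param rows consensus table (needs `gene_id`).
#' @param catalog vector of documented gene ids, or `NULL`.
#' @return `rows` with a logical `documented` column.
#' @export
annotate_catalog <- function(rows, catalog = NULL) {
  rows$documented <- if (is.null(catalog)) {
    rep(FALSE, nrow(rows))
  } else {
    rows$gene_id %in% catalog
  }
  rows
}
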