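# Hypergeometric over-representation of a query gene list against GMT gene
# sets, with Holm (Bonferroni step-down) correction.

#' Exact hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability that a
#' uniform draw of `n` genes from a background of `N` hits at least `k` of a
#' term's `K` members. Evaluated through the log-space tail of
#' [stats::phyper()].
#'
#' @param k observed overlap.
#' @param K term size within the background.
#' @param n query size.
#' @param N background size.
#' @return the tail probability in (0, 1].
#' @export
hypergeom_tail_p <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 1 || K > N || n > N || k > min(K, n)) {
    fail("inconsistent counts: k=%d K=%d n=%d N=%d", k, K, n, N)
  }
  if (k == 0) return(1)
  min(1, exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)))
}

#' Holm (Bonferroni step-down) adjustment
#' @param pvalues numeric vector in (0, 1].
#' @return adjusted p-values in input order; elementwise >= raw p and
#'   <= plain Bonferroni.
#' @export
holm_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1)) {
    fail("p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "holm")
}

#' Hypergeometric enrichment of a query gene list against a GMT collection
#'
#' Term members are intersected with the background before the term size `K`
#' is computed; terms with `K = 0` are not tested. Both the Holm step-down
#' and the plain Bonferroni correction are reported.
#'
#' @param query gene-id vector, a subset of `background`.
#' @param collection a `gene_set_collection` from [read_gmt()].
#' @param background background gene universe.
#' @return data.frame `term_id, description, k, K, n, N, pvalue, holm_p,
#'   bonferroni_p`, sorted by `pvalue`.
#' @export
enrich_terms <- function(query, collection, background) {
  background <- unique(background)
  query <- unique(query)
  if (length(query) == 0) fail("`query` is empty")
  extra <- setdiff(query, background)
  if (length(extra) > 0) {
    fail("query gene(s) outside the background: %s",
         paste(head(extra, 10), collapse = ", "))
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(collection), function(term) {
    members <- intersect(collection[[term]]$members, background)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, query))
    data.frame(term_id = term,
               description = collection[[term]]$description,
               k = k, K = K, n = n, N = N,
               pvalue = hypergeom_tail_p(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows) > 0) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    NULL
  }
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(term_id = character(0), description = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), pvalue = numeric(0),
                      holm_p = numeric(0), bonferroni_p = numeric(0)))
  }
  out$holm_p <- holm_adjust(out$pvalue)
  out$bonferroni_p <- bonferroni_adjust(out$pvalue)
  out <- out[order(out$pvalue), , drop = FALSE]
  rownames(out) <- NULL
  out
}
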