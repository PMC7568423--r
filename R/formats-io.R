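# On-disk formats. Internal coordinates are always 1-based inclusive; the
# only 0-based surface is BED on disk (handled by rtracklayer).

GWAS_COLS <- c("rsid", "chrom", "pos", "ea", "oa", "beta", "se", "pvalue", "n")

#' Read GWAS summary statistics from TSV
#'
#' Expects a header with columns `rsid chrom pos ea oa beta se pvalue n`
#' (remappable through `col_map` for real-world dialects). Rows violating the
#' record invariants (`pos >= 1`, `pvalue` in (0, 1], `se > 0`) abort the
#' read with their line numbers; a beta/se/p inconsistency beyond 10%
#' relative tolerance is reported as a warning, not an error.
#'
#' @param path file path.
#' @param col_map named character vector mapping canonical names to the
#'   file's column names, e.g. `c(rsid = "SNP", pvalue = "P")`.
#' @return a validated GWAS data.frame.
#' @export
read_gwas_tsv <- function(path, col_map = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      j <- match(col_map[[canon]], names(d))
      if (is.na(j)) fail("col_map column `%s` not found in %s", col_map[[canon]], path)
      names(d)[j] <- canon
    }
  }
  missing <- setdiff(GWAS_COLS, names(d))
  if (length(missing) > 0) {
    fail("GWAS file %s is missing mandatory column(s): %s",
         path, paste(missing, collapse = ", "))
  }
  d <- d[GWAS_COLS]
  if (nrow(d) == 0) return(d)

  for (col in c("pos", "beta", "se", "pvalue", "n")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad) > 0) {
      fail("unparsable `%s` at line(s) %s of %s", col,
           paste(bad + 1L, collapse = ", "), path)
    }
    d[[col]] <- v
  }
  reject_rows(d$pos < 1, "pos out of range (must be >= 1)", path)
  reject_rows(!(d$pvalue > 0 & d$pvalue <= 1), "pvalue out of (0,1]", path)
  reject_rows(!(d$se > 0), "se must be > 0", path)

  # consistency flag: two-sided normal p of beta/se should match p within 10%
  ok <- is.finite(d$beta) & is.finite(d$se) & is.finite(d$pvalue)
  implied <- z_to_p(d$beta[ok] / d$se[ok])
  off <- abs(implied - d$pvalue[ok]) > 0.1 * pmax(d$pvalue[ok], implied)
  if (any(off)) {
    warning(sum(off), " row(s) in ", path,
            " have pvalue inconsistent with beta/se (>10% relative)",
            call. = FALSE)
  }
  d$pos <- as.integer(d$pos)
  d$n <- as.integer(d$n)
  d
}

reject_rows <- function(bad, why, path) {
  bad <- which(bad)
  if (length(bad) > 0) {
    fail("%s at line(s) %s of %s", why,
         paste(bad + 1L, collapse = ", "), path)  # +1 for the header line
  }
}

#' Write GWAS summary statistics to TSV
#' @param gwas a GWAS data.frame.
#' @param path output path.
#' @export
write_gwas_tsv <- function(gwas, path) {
  write.table(gwas[GWAS_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

EQTL_COLS <- c("rsid", "gene_id", "pvalue", "beta", "dataset_label", "cis_trans")

#' Read / write an eQTL association table (TSV)
#'
#' Columns: `rsid gene_id pvalue beta dataset_label cis_trans`. `cis_trans`
#' may be omitted on read and recomputed later via [classify_cis_trans()].
#'
#' @param path file path.
#' @return a validated eQTL data.frame.
#' @export
read_eqtl_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- setdiff(c("rsid", "gene_id", "pvalue", "beta", "dataset_label"),
                  names(d))
  if (length(need) > 0) {
    fail("eQTL file %s is missing mandatory column(s): %s",
         path, paste(need, collapse = ", "))
  }
  if (nrow(d) > 0) {
    d$pvalue <- as.numeric(d$pvalue)
    reject_rows(!(d$pvalue > 0 & d$pvalue <= 1), "pvalue out of (0,1]", path)
    reject_rows(is.na(d$dataset_label) | d$dataset_label == "",
                "empty dataset_label", path)
  }
  if (!"cis_trans" %in% names(d)) d$cis_trans <- NA_character_
  d[EQTL_COLS]
}

#' @rdname read_eqtl_tsv
#' @param eqtl an eQTL data.frame.
#' @export
write_eqtl_tsv <- function(eqtl, path) {
  write.table(eqtl[intersect(EQTL_COLS, names(eqtl))], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify eQTL pairs as cis or trans
#'
#' A pair is cis when the SNP lies within the gene span extended by
#' `window_bp` on both sides (1 Mb by default, the conventional cis bound);
#' anything else — including other chromosomes — is trans.
#'
#' @param eqtl eQTL data.frame with `rsid`, `gene_id`.
#' @param genes gene models (`gene_id, chrom, start, end`, 1-based inclusive).
#' @param snps SNP map (`rsid, chrom, pos`).
#' @param window_bp cis window in bp.
#' @return the eQTL data.frame with `cis_trans` filled.
#' @export
classify_cis_trans <- function(eqtl, genes, snps, window_bp = 1e6) {
  gi <- match(eqtl$gene_id, genes$gene_id)
  si <- match(eqtl$rsid, snps$rsid)
  if (anyNA(gi)) fail("unknown gene id(s): %s",
                      paste(unique(eqtl$gene_id[is.na(gi)]), collapse = ", "))
  if (anyNA(si)) fail("unknown rsid(s): %s",
                      paste(unique(eqtl$rsid[is.na(si)]), collapse = ", "))
  same_chr <- genes$chrom[gi] == snps$chrom[si]
  inside <- snps$pos[si] >= genes$start[gi] - window_bp &
    snps$pos[si] <= genes$end[gi] + window_bp
  eqtl$cis_trans <- ifelse(same_chr & inside, "cis", "trans")
  eqtl
}

#' Read gene models from a BED file
#'
#' BED is 0-based half-open on disk; models are returned 1-based inclusive
#' (`start = bed_start + 1`, `end = bed_end`). Requires a name column
#' (BED4+); duplicate gene ids are an error.
#'
#' @param path BED file path.
#' @return data.frame `gene_id, chrom, start, end`.
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm) || anyNA(nm)) fail("BED file %s lacks gene names (column 4)", path)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup) > 0) {
    fail("duplicate gene_id(s) in %s: %s", path, paste(dup, collapse = ", "))
  }
  d <- data.frame(
    gene_id = nm,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),  # rtracklayer already shifts to 1-based
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  bad <- which(d$start > d$end)
  if (length(bad) > 0) {
    fail("start > end for gene(s): %s", paste(d$gene_id[bad], collapse = ", "))
  }
  d
}

#' Write gene models to BED
#' @param genes data.frame `gene_id, chrom, start, end` (1-based inclusive).
#' @param path output path.
#' @export
write_gene_bed <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    name = genes$gene_id
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one term per line, tab-separated fields
#' `term<TAB>description<TAB>member...`. Members duplicated within a term are
#' collapsed keeping first occurrence order. Lines with fewer than 3 fields
#' are a format error reported with their line number.
#'
#' @param path GMT file path.
#' @return a `gene_set_collection`: named list of
#'   `list(description=, members=)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      fail("GMT line %d of %s has %d field(s); need term, description, members",
           i, path, length(f))
    }
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) fail("GMT line %d of %s has no members", i, path)
    sets[[f[[1]]]] <- list(description = f[[2]], members = members)
  }
  structure(sets, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param collection a `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(term) {
    s <- collection[[term]]
    paste(c(term, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a genotype dosage matrix (TSV, samples x SNPs)
#'
#' First column `sample_id`, remaining columns one per SNP in map order;
#' entries must lie in `[0, 2]` with no missing values.
#'
#' @param path file path.
#' @return a `genotype_panel` object.
#' @export
read_genotype_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "sample_id") fail("first column of %s must be `sample_id`", path)
  m <- as.matrix(d[-1])
  rownames(m) <- d$sample_id
  storage.mode(m) <- "double"
  if (anyNA(m)) fail("missing dosage entries in %s", path)
  if (any(m < 0 | m > 2)) fail("dosages outside [0, 2] in %s", path)
  structure(list(sample_ids = rownames(m), snp_ids = colnames(m), dosage = m),
            class = "genotype_panel")
}

#' @rdname read_genotype_tsv
#' @param panel a `genotype_panel`.
#' @export
write_genotype_tsv <- function(panel, path) {
  d <- data.frame(sample_id = panel$sample_ids, panel$dosage,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an expression matrix with sample metadata
#'
#' The matrix travels as CSV (genes x samples, first column `gene_id`), the
#' group labels as a two-column TSV (`sample_id`, `group`). Every sample must
#' carry a group label; duplicate gene ids are an error.
#'
#' @param expr_path CSV path for the matrix.
#' @param meta_path TSV path for the sample metadata.
#' @return an `expression_matrix` object.
#' @export
read_expression <- function(expr_path, meta_path) {
  d <- utils::read.csv(expr_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "gene_id") fail("first column of %s must be `gene_id`", expr_path)
  if (anyDuplicated(d$gene_id)) {
    fail("duplicate gene id(s) in %s: %s", expr_path,
         paste(unique(d$gene_id[duplicated(d$gene_id)]), collapse = ", "))
  }
  m <- as.matrix(d[-1])
  rownames(m) <- d$gene_id
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  miss <- setdiff(colnames(m), meta$sample_id)
  if (length(miss) > 0) {
    fail("sample(s) without group label in %s: %s", meta_path,
         paste(miss, collapse = ", "))
  }
  new_expression_matrix(m, meta)
}

#' @rdname read_expression
#' @param em an `expression_matrix`.
#' @export
write_expression <- function(em, expr_path, meta_path) {
  d <- data.frame(gene_id = rownames(em$expr), em$expr,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(d, expr_path, row.names = FALSE, quote = FALSE)
  write.table(em$meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(expr_path)
}

#' Serialize the ground truth of a synthetic run to JSON
#' @param truth a `sim_truth`.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(seed = truth$seed, config = truth$config,
         planted_genes = truth$planted_genes,
         planted_snps = truth$planted_snps, deg_genes = truth$deg_genes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
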