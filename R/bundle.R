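#' Bundle a count matrix with its sample metadata
#'
#' The central expression container: a non-negative integer count matrix
#' (genes x samples) plus one metadata row per sample (`sample`, `tissue`,
#' `condition`, `time`, `replicate`) and per-sample normalization factors
#' (default 1).
#'
#' @param counts Matrix (or data frame with a `gene` first column) of
#'   non-negative counts; columns are samples.
#' @param samples Tibble of per-sample metadata; must contain a `sample`
#'   column matching `colnames(counts)` in order.
#' @param norm_factors Optional positive per-sample scaling factors.
#' @return An `expr_bundle` object.
#' @export
expression_bundle <- function(counts, samples, norm_factors = NULL) {
  if (is.data.frame(counts)) {
    gene <- counts[[1]]
    counts <- as.matrix(counts[, -1, drop = FALSE])
    rownames(counts) <- gene
  }
  counts <- as.matrix(counts)
  samples <- as_tibble(samples)
  if (!"sample" %in% names(samples)) stopf("metadata must have a 'sample' column")
  if (ncol(counts) != nrow(samples)) {
    stopf("metadata rows (%d) must match count columns (%d)",
      nrow(samples), ncol(counts))
  }
  if (!identical(colnames(counts), as.character(samples$sample))) {
    stopf("metadata sample ids must match count column names in order")
  }
  if (any(counts < 0)) stopf("counts must be non-negative")
  norm_factors <- norm_factors %||% rep(1, ncol(counts))
  if (any(norm_factors <= 0)) stopf("norm_factors must be positive")
  structure(
    list(counts = counts, samples = samples, norm_factors = norm_factors),
    class = "expr_bundle"
  )
}

#' @export
print.expr_bundle <- function(x, ...) {
  cat(sprintf(
    "<expr_bundle> %d genes x %d samples (%s)\n",
    nrow(x$counts), ncol(x$counts),
    paste(unique(x$samples$condition), collapse = "/")
  ))
  invisible(x)
}

#' Counts per million with optional TMM scaling
#'
#' `cpm[g, s] = counts[g, s] / (libsize_s * factor_s) * 1e6`, the effective
#' library size being the raw column sum times the sample's normalization
#' factor. When `log = TRUE` a half-count offset is added before division
#' (recorded in the provenance attribute) and base-2 logs are returned.
#'
#' @param x An `expr_bundle` or a count matrix.
#' @param norm_factors Per-sample factors; defaults to the bundle's factors
#'   (or 1). Use [tmm_factors()] to compute TMM factors.
#' @param log Return `log2(cpm)` computed with a +0.5 count offset.
#' @param ... Passed between methods.
#' @return A genes x samples matrix with attribute `provenance`.
#' @export
cpm <- function(x, ...) UseMethod("cpm")

#' @rdname cpm
#' @export
cpm.expr_bundle <- function(x, norm_factors = NULL, log = FALSE, ...) {
  cpm.default(x$counts, norm_factors = norm_factors %||% x$norm_factors, log = log)
}

#' @rdname cpm
#' @export
cpm.default <- function(x, norm_factors = NULL, log = FALSE, ...) {
  x <- as.matrix(x)
  lib <- colSums(x)
  if (any(lib == 0)) {
    stopf("zero library size in sample(s): %s",
      paste(colnames(x)[lib == 0], collapse = ", "))
  }
  nf <- norm_factors %||% rep(1, ncol(x))
  eff <- lib * nf
  if (log) {
    out <- log2(sweep(x + 0.5, 2, eff, "/") * 1e6)
  } else {
    out <- sweep(x, 2, eff, "/") * 1e6
  }
  attr(out, "provenance") <- list(
    tmm_applied = !is.null(norm_factors) && !all(nf == 1),
    log = log, offset = if (log) 0.5 else 0
  )
  out
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Between-sample scaling factors computed by the TMM method: each factor is
#' `2^` the precision-weighted trimmed mean of gene-wise log ratios (M-values)
#' against a reference sample, trimming the stated fractions of extreme M and
#' A values, then rescaled so the factors' geometric mean is 1. The
#' computation is delegated to [edgeR::calcNormFactors()]; the default trim
#' fractions (30% of M, 5% of A) are the method's published defaults.
#'
#' @param x An `expr_bundle` or count matrix (>= 2 samples).
#' @param reference Optional reference column index; by default the sample
#'   whose 75th-percentile count fraction is closest to the mean.
#' @param trim_m,trim_a Trim fractions for M and A values.
#' @return Numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(x, reference = NULL, trim_m = 0.30, trim_a = 0.05) {
  counts <- if (inherits(x, "expr_bundle")) x$counts else as.matrix(x)
  if (ncol(counts) < 2L) stopf("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stopf("zero library size in sample(s): %s",
      paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  f <- edgeR::calcNormFactors(counts,
    lib.size = lib, method = "TMM",
    refColumn = reference, logratioTrim = trim_m, sumTrim = trim_a
  )
  if (any(!is.finite(f))) {
    warnf("sample(s) %s share no co-expressed genes with the reference; factor set to 1",
      paste(colnames(counts)[!is.finite(f)], collapse = ", "))
    f[!is.finite(f)] <- 1
    f <- f / geo_mean(f)
  }
  unname(f)
}

#' Filter weakly expressed genes
#'
#' Keeps genes with at least `min_cpm` counts per million in at least
#' `min_samples` libraries. Idempotent.
#'
#' @param x A cpm matrix (genes x samples) or an `expr_bundle` (filtered on
#'   its TMM-free cpm by default).
#' @param min_cpm,min_samples Filter thresholds.
#' @param ... Passed between methods.
#' @return Same type as `x`, restricted to kept genes; the kept gene ids are
#'   in attribute `kept_genes`.
#' @export
filter_low_expression <- function(x, min_cpm = 1, min_samples = 5, ...) {
  UseMethod("filter_low_expression")
}

#' @rdname filter_low_expression
#' @export
filter_low_expression.default <- function(x, min_cpm = 1, min_samples = 5, ...) {
  x <- as.matrix(x)
  keep <- rowSums(x >= min_cpm) >= min_samples
  out <- x[keep, , drop = FALSE]
  attr(out, "kept_genes") <- rownames(out)
  out
}

#' @rdname filter_low_expression
#' @export
filter_low_expression.expr_bundle <- function(x, min_cpm = 1, min_samples = 5, ...) {
  keep <- rowSums(cpm(x) >= min_cpm) >= min_samples
  out <- expression_bundle(x$counts[keep, , drop = FALSE], x$samples, x$norm_factors)
  attr(out, "kept_genes") <- rownames(out$counts)
  out
}

#' Group-mean (mesor-level) expression per gene
#'
#' Arithmetic mean of normalized expression over the samples of a metadata
#' group, e.g. the mesor-level expression of a gene in one tissue.
#'
#' @param bundle An `expr_bundle`.
#' @param by Metadata columns to group by (default `"tissue"`).
#' @param norm_factors,log Passed to [cpm()].
#' @return A tibble with `gene`, the grouping columns and `mesor`; empty
#'   groups are absent, and a gene absent from the matrix is an error.
#' @export
mesor_table <- function(bundle, by = "tissue", norm_factors = NULL, log = FALSE) {
  stopifnot(inherits(bundle, "expr_bundle"))
  m <- cpm(bundle, norm_factors = norm_factors, log = log)
  long <- as_tibble(m, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "value") |>
    left_join(bundle$samples, by = "sample")
  long |>
    group_by(across(dplyr::all_of(c("gene", by)))) |>
    summarise(mesor = mean(.data$value), .groups = "drop")
}

#' @rdname mesor_table
#' @param gene Gene id.
#' @param tissue Tissue label.
#' @param condition Optional condition label to restrict to.
#' @return `condition_mesor()`: a single mean; `NA` with a warning for an
#'   empty group.
#' @export
condition_mesor <- function(bundle, gene, tissue, condition = NULL,
                            norm_factors = NULL, log = FALSE) {
  stopifnot(inherits(bundle, "expr_bundle"))
  if (!gene %in% rownames(bundle$counts)) stopf("gene '%s' not in matrix", gene)
  sel <- bundle$samples$tissue == tissue
  if (!is.null(condition)) sel <- sel & bundle$samples$condition == condition
  if (!any(sel)) {
    warnf("empty group (tissue=%s); mesor undefined", tissue)
    return(NA_real_)
  }
  m <- cpm(bundle, norm_factors = norm_factors, log = log)
  mean(m[gene, sel])
}

#' Read / write an expression bundle as TSV
#'
#' The counts TSV has a header row of sample ids and a first column `gene`;
#' the metadata TSV is one row per sample.
#'
#' @param counts_path,meta_path TSV paths.
#' @return `read_bundle()` returns an `expr_bundle`.
#' @export
read_bundle <- function(counts_path, meta_path) {
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE, comment = "#")
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, comment = "#")
  expression_bundle(counts, meta)
}

#' @rdname read_bundle
#' @param bundle An `expr_bundle`.
#' @export
write_bundle <- function(bundle, counts_path, meta_path) {
  readr::write_tsv(
    as_tibble(bundle$counts, rownames = "gene"), counts_path
  )
  readr::write_tsv(bundle$samples, meta_path)
  invisible(c(counts_path, meta_path))
}
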