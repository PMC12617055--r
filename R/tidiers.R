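#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a differential-expression result
#'
#' The result is already a tibble; `tidy()` returns it with the class
#' attributes stripped, `glance()` condenses it to one row.
#'
#' @param x An `sbg_de` object from [run_de()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sbg_de <- function(x, ...) {
  out <- x
  class(out) <- c("tbl_df", "tbl", "data.frame")
  attr(out, "species") <- NULL
  attr(out, "model") <- NULL
  attr(out, "alpha") <- NULL
  attr(out, "size_factors") <- NULL
  out
}

#' @rdname tidy.sbg_de
#' @export
glance.sbg_de <- function(x, ...) {
  tibble::tibble(
    species = attr(x, "species"),
    model = attr(x, "model"),
    alpha = attr(x, "alpha"),
    n_genes = nrow(x),
    n_tested = sum(!is.na(x$padj)),
    n_fbg = sum(x$bias_class == "FBG", na.rm = TRUE),
    n_mbg = sum(x$bias_class == "MBG", na.rm = TRUE),
    prop_sbg = (n_fbg + n_mbg) / n_tested)
}

#' Tidy an RRHO map into a long tibble of grid cells
#'
#' @param x An `rrho_map`.
#' @param ... Unused.
#' @return Tibble with one row per grid cell: `threshold_a`, `threshold_b`,
#'   `overlap`, `pvalue`, `signed_score`, and BY-corrected columns when
#'   present.
#' @export
tidy.rrho_map <- function(x, ...) {
  k <- length(x$thresholds)
  out <- tibble::tibble(
    threshold_a = rep(x$thresholds, times = k),
    threshold_b = rep(x$thresholds, each = k),
    overlap = as.vector(x$overlap),
    pvalue = as.vector(x$pvalue),
    signed_score = as.vector(x$signed_score))
  if (!is.null(x$pvalue_by)) {
    out$pvalue_by <- as.vector(x$pvalue_by)
    out$signed_score_by <- as.vector(x$signed_score_by)
  }
  out
}

#' @rdname tidy.rrho_map
#' @export
glance.rrho_map <- function(x, ...) {
  tibble::tibble(
    n_genes = x$n_genes,
    stepsize = x$stepsize,
    n_cells = length(x$pvalue),
    max_signed_score = max(x$signed_score),
    min_pvalue = min(x$pvalue),
    min_pvalue_by = if (!is.null(x$pvalue_by)) min(x$pvalue_by) else NA_real_)
}

#' @export
print.rrho_map <- function(x, ...) {
  cat(sprintf("<rrho_map> %d shared genes, stepsize %d, %dx%d grid; peak signed score %.2f%s\n",
              x$n_genes, x$stepsize, length(x$thresholds), length(x$thresholds),
              max(x$signed_score),
              if (is.null(x$pvalue_by)) " (uncorrected)" else " (BY-corrected available)"))
  invisible(x)
}
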