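#' Filter lowly expressed genes
#'
#' Keeps a gene when its count reaches `min_count` in strictly more than
#' `min_samples_exclusive` samples (defaults: at least 5 reads in more than
#' three samples, i.e., four or more samples). Row order is preserved.
#'
#' @param counts Gene x sample count matrix.
#' @param min_count Minimum per-sample read count.
#' @param min_samples_exclusive Gene kept when
#'   `#{samples with count >= min_count} > min_samples_exclusive`.
#' @return The filtered count matrix.
#' @export
filter_low_counts <- function(counts, min_count = 5, min_samples_exclusive = 3) {
  stopifnot(min_count >= 0, min_samples_exclusive >= 0)
  keep <- rowSums(counts >= min_count) > min_samples_exclusive
  if (!any(keep)) warning("no genes pass the low-count filter")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample size factor: the median, over reference genes, of that
#' sample's count divided by the gene's geometric mean across samples.
#' Reference genes are those with a positive count in every sample.
#'
#' @param counts Gene x sample count matrix.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors_median_of_ratios <- function(counts) {
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no gene has positive counts in every sample; filter low counts first")
  logc <- log(counts[ref, , drop = FALSE])
  log_gm <- rowMeans(logc)
  sf <- apply(logc, 2, function(col) exp(stats::median(col - log_gm)))
  names(sf) <- colnames(counts)
  sf
}

#' Transcripts per kilobase million
#'
#' Per sample, each gene's count is divided by its length in kb, then the
#' column is scaled to sum to 1e6.
#'
#' @param counts Gene x sample count matrix.
#' @param annotation Annotation tibble carrying `gene_id` and `length` (bp)
#'   for every counted gene.
#' @return Numeric matrix of TPM values, same dimnames as `counts`.
#' @export
tpm <- function(counts, annotation) {
  idx <- match(rownames(counts), annotation$gene_id)
  if (anyNA(idx))
    stop("annotation missing counted gene(s): ",
         paste(utils::head(rownames(counts)[is.na(idx)], 5), collapse = ", "))
  len_kb <- annotation$length[idx] / 1000
  if (any(len_kb <= 0)) stop("gene lengths must be positive")
  rate <- counts / len_kb
  denom <- colSums(rate)
  if (any(denom == 0))
    stop("sample(s) with all-zero counts, TPM undefined: ",
         paste(colnames(counts)[denom == 0], collapse = ", "))
  sweep(rate, 2, denom, "/") * 1e6
}

#' Log2 transform with pseudocount
#'
#' @param values Non-negative numeric matrix or vector.
#' @param pseudocount Added before the log (default 1, so 0 maps to 0).
#' @return `log2(values + pseudocount)`.
#' @export
log2_with_pseudocount <- function(values, pseudocount = 1) {
  if (any(values < 0, na.rm = TRUE)) stop("values must be non-negative")
  log2(values + pseudocount)
}

#' Sample-level PCA for quality control
#'
#' Centred principal component analysis of samples on the `top_genes`
#' highest-variance genes of a log-scale expression matrix.
#'
#' @param log_expression Gene x sample matrix on a log scale (e.g.
#'   `log2_with_pseudocount` of normalised counts).
#' @param n_components Number of components to return.
#' @param top_genes Number of top-variance genes used (all if fewer).
#' @return List of class `sbg_pca`: `coordinates` tibble
#'   (`sample_id`, `PC1`, ...) and `variance_explained` (proportions,
#'   non-increasing, summing to <= 1).
#' @export
pca_qc <- function(log_expression, n_components = 2, top_genes = 500) {
  if (ncol(log_expression) < 2) stop("PCA needs at least 2 samples")
  if (n_components > min(dim(log_expression)))
    stop("n_components exceeds matrix dimensions")
  v <- apply(log_expression, 1, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(top_genes, nrow(log_expression)))]
  pc <- stats::prcomp(t(log_expression[keep, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- tibble::as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  coords <- dplyr::bind_cols(tibble::tibble(sample_id = colnames(log_expression)),
                             coords)
  structure(list(coordinates = coords,
                 variance_explained = ve[seq_len(n_components)]),
            class = "sbg_pca")
}
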