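#' Degree of differential expression profile
#'
#' `dde = -log10(p) * sign(lfc)`: negative values mark overexpression in
#' females, positive in males. p-values are floored at 1e-300 before the
#' log; a zero LFC gives `dde = 0`; genes with missing p are dropped. Ranks
#' run from 1 = most female-biased (most negative dde), ties broken by
#' gene id for determinism.
#'
#' @param de DE result tibble with `gene_id`, `lfc` and p columns.
#' @param p_source `"padj"` (default, matching a BH-corrected profile) or
#'   `"pvalue"`.
#' @param p_floor Lower p bound before taking logs (default 1e-300).
#' @return Tibble of class `dde_profile`: `gene_id`, `dde`, `rank`.
#' @export
compute_dde <- function(de, p_source = c("padj", "pvalue"), p_floor = 1e-300) {
  p_source <- match.arg(p_source)
  p <- de[[p_source]]
  keep <- !is.na(p) & !is.na(de$lfc)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " gene(s) without a p-value excluded from the DDE profile")
  p <- pmax(p[keep], p_floor)
  dde <- -log10(p) * sign(de$lfc[keep])
  out <- tibble::tibble(gene_id = de$gene_id[keep], dde = dde)
  out <- out[order(out$dde, out$gene_id), ]
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("dde_profile", class(tibble::tibble())))
}

#' Default RRHO step size
#'
#' Square root of the number of genes analysed, rounded up.
#'
#' @param n_genes Number of genes (>= 1).
#' @return Integer step size.
#' @export
default_stepsize <- function(n_genes) {
  stopifnot(n_genes >= 1)
  as.integer(ceiling(sqrt(n_genes)))
}

#' Rank-rank hypergeometric overlap map
#'
#' Both profiles are restricted to their shared genes and ranked by dde
#' (rank 1 = most female-biased). For each threshold pair
#' `(i * stepsize, j * stepsize)` the overlap between the two top lists is
#' counted and scored with hypergeometric tail probabilities: the stored
#' cell p-value is the smaller of the over- and under-enrichment tails, and
#' the signed score is `-log10(p)` with a positive sign for over-enrichment
#' (concordance along the diagonal) and negative for depletion.
#'
#' @param profile_a,profile_b [compute_dde()] profiles.
#' @param stepsize Positive integer, or `NULL` for [default_stepsize()] on
#'   the shared gene count.
#' @return Object of class `rrho_map`: list with `stepsize`, `n_genes`,
#'   `thresholds`, matrices `overlap`, `pvalue`, `signed_score` (rows:
#'   thresholds in A, columns: thresholds in B), and `genes`.
#' @export
rrho_map <- function(profile_a, profile_b, stepsize = NULL) {
  shared <- intersect(profile_a$gene_id, profile_b$gene_id)
  n <- length(shared)
  if (n < 2) stop("need >= 2 shared genes for an RRHO map")
  a <- profile_a[match(shared, profile_a$gene_id), ]
  b <- profile_b[match(shared, profile_b$gene_id), ]
  ra <- rank_dde(a)
  rb <- rank_dde(b)
  if (is.null(stepsize)) stepsize <- default_stepsize(n)
  stopifnot(stepsize >= 1)
  k <- ceiling(n / stepsize)
  thresholds <- pmin(seq_len(k) * stepsize, n)

  # 2-D dominance counts via a binned cumulative histogram
  bin_a <- findInterval(ra, thresholds, left.open = TRUE) + 1L
  bin_b <- findInterval(rb, thresholds, left.open = TRUE) + 1L
  h <- matrix(0, k, k)
  for (g in seq_len(n)) h[bin_a[g], bin_b[g]] <- h[bin_a[g], bin_b[g]] + 1
  overlap <- apply(apply(h, 2, cumsum), 1, cumsum)
  overlap <- t(overlap)

  ta <- matrix(thresholds, k, k)
  tb <- matrix(thresholds, k, k, byrow = TRUE)
  p_over <- stats::phyper(overlap - 1, ta, n - ta, tb, lower.tail = FALSE)
  p_under <- stats::phyper(overlap, ta, n - ta, tb, lower.tail = TRUE)
  over_wins <- p_over <= p_under
  pvalue <- ifelse(over_wins, p_over, p_under)
  signed <- ifelse(over_wins, 1, -1) * -log10(pmax(pvalue, 1e-300))

  structure(list(stepsize = as.integer(stepsize), n_genes = n,
                 thresholds = thresholds, overlap = overlap,
                 pvalue = pvalue, signed_score = signed,
                 genes = shared),
            class = "rrho_map")
}

# ranks within a shared-gene profile: 1 = most female-biased, gene-id ties
rank_dde <- function(profile) {
  ord <- order(profile$dde, profile$gene_id)
  r <- integer(nrow(profile))
  r[ord] <- seq_len(nrow(profile))
  r
}

#' Benjamini-Yekutieli correction of an RRHO map
#'
#' Applies the BY step-up procedure over all grid cells' stored p-values and
#' recomputes the signed scores from the corrected values.
#'
#' @param map An [rrho_map()].
#' @return The map with `pvalue_by` and `signed_score_by` matrices added.
#' @export
adjust_by <- function(map) {
  stopifnot(inherits(map, "rrho_map"))
  padj <- stats::p.adjust(as.vector(map$pvalue), method = "BY")
  padj <- matrix(padj, nrow = nrow(map$pvalue))
  map$pvalue_by <- padj
  map$signed_score_by <- sign(map$signed_score) * -log10(pmax(padj, 1e-300))
  map
}

#' Sign concordance and rank correlation between two DDE profiles
#'
#' On the shared genes: Spearman correlation of the dde vectors, and the
#' proportion of genes whose dde sign agrees among genes with a nonzero sign
#' in both species.
#'
#' @param profile_a,profile_b [compute_dde()] profiles.
#' @param min_shared Minimum shared genes (default 10).
#' @return One-row tibble: `n_shared`, `n_signed`, `proportion_concordant`,
#'   `spearman_rho`.
#' @export
concordance_summary <- function(profile_a, profile_b, min_shared = 10) {
  shared <- intersect(profile_a$gene_id, profile_b$gene_id)
  if (length(shared) < min_shared)
    stop("need >= ", min_shared, " shared genes, got ", length(shared))
  da <- profile_a$dde[match(shared, profile_a$gene_id)]
  db <- profile_b$dde[match(shared, profile_b$gene_id)]
  if (all(da == 0) || all(db == 0)) {
    rho <- NA_real_; prop <- NA_real_; n_signed <- 0L
  } else {
    rho <- stats::cor(da, db, method = "spearman")
    signed <- sign(da) != 0 & sign(db) != 0
    n_signed <- sum(signed)
    prop <- if (n_signed > 0) mean(sign(da[signed]) == sign(db[signed])) else NA_real_
  }
  tibble::tibble(n_shared = length(shared), n_signed = n_signed,
                 proportion_concordant = prop, spearman_rho = rho)
}

#' Quadrant-based concordance of a corrected RRHO map
#'
#' Alternative concordance readout: the fraction of genes falling in
#' significantly enriched concordant corner cells (both top = female-biased
#' corner, both bottom = male-biased corner) of the BY-corrected map.
#'
#' @param map An [rrho_map()] after [adjust_by()].
#' @param alpha Significance threshold on BY-corrected cell p (default 0.05).
#' @return One-row tibble: `concordant_female_signal`,
#'   `concordant_male_signal` - the strongest BY-corrected signed score in
#'   each concordant corner quadrant, and `significant` flags at `alpha`.
#' @export
rrho_quadrant_summary <- function(map, alpha = 0.05) {
  stopifnot(inherits(map, "rrho_map"), !is.null(map$pvalue_by))
  k <- length(map$thresholds)
  half <- seq_len(floor(k / 2))
  upper <- map$signed_score_by[half, half, drop = FALSE]            # both female tops
  lower <- map$signed_score_by[k + 1 - half, k + 1 - half, drop = FALSE]
  p_up <- map$pvalue_by[half, half, drop = FALSE]
  p_lo <- map$pvalue_by[k + 1 - half, k + 1 - half, drop = FALSE]
  tibble::tibble(
    concordant_female_signal = max(upper),
    concordant_male_signal = max(lower),
    female_significant = any(p_up < alpha & upper > 0),
    male_significant = any(p_lo < alpha & lower > 0))
}
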