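#' Sample-size correction factor for the expression-divergence statistic
#'
#' `f = sqrt((m*N - 1) / (m*N - m))`, where `m` is the focal sample size and
#' `N` the reference (most common) sample size, 3 by default. With
#' `m = N = 3`, `f = sqrt(8/6)`, about 1.154701.
#'
#' @param m Focal sample size (>= 1).
#' @param N Reference sample size (default 3).
#' @return The correction factor `f`.
#' @export
sample_size_factor <- function(m, N = 3) {
  if (any(m < 1)) stop("sample size m must be >= 1")
  if (any(m * N <= m)) stop("m*N must exceed m (need N > 1)")
  sqrt((m * N - 1) / (m * N - m))
}

#' Relative expression range of the focal species
#'
#' `r = (max - min) / mean` over the focal replicates; `NA` when the mean is
#' zero.
#'
#' @param values Numeric vector of >= 2 focal replicate values
#'   (log2-transformed TPM).
#' @return The relative range `r`.
#' @export
relative_range <- function(values) {
  if (length(values) < 2) stop("relative range needs >= 2 replicates")
  m <- mean(values)
  if (m == 0) return(NA_real_)
  (max(values) - min(values)) / m
}

#' Relative expression divergence between focal and related species
#'
#' `d = (mean_focal - mean_related) / mean_focal`; `NA` when the focal mean
#' is zero.
#'
#' @param focal_values,related_values Replicate vectors (log2 TPM).
#' @return The relative divergence `d`.
#' @export
relative_divergence <- function(focal_values, related_values) {
  if (length(focal_values) < 1 || length(related_values) < 1)
    stop("both species need >= 1 replicate value")
  mf <- mean(focal_values)
  if (mf == 0) return(NA_real_)
  (mf - mean(related_values)) / mf
}

#' The delta-x expression-divergence statistic for one gene
#'
#' `delta_x = d / (f * r)`: divergence relative to the focal species' level,
#' scaled by its within-species range (corrected for sample size). Values
#' above 1 flag putative directional selection towards higher expression
#' ("up"), below -1 towards lower expression ("down"). Inputs are expected
#' to be log2(TPM + pseudocount) replicate vectors.
#'
#' Degenerate cases: `d = 0` gives `delta_x = 0` (class "none") even when
#' `r = 0`; `r = 0` with `d != 0` or a zero focal mean gives class
#' "undefined" with `delta_x = NA`.
#'
#' @param focal_values,related_values Replicate vectors (log2 TPM).
#' @param m Focal sample size (default `length(focal_values)`).
#' @param N Reference sample size (default 3).
#' @return One-row tibble: `d`, `r`, `f`, `delta_x`, `selection_class`.
#' @examples
#' delta_x(c(5, 6, 7), c(3, 3, 3))   # d = 0.5, r = 1/3, class "up"
#' @export
delta_x <- function(focal_values, related_values,
                    m = length(focal_values), N = 3) {
  d <- relative_divergence(focal_values, related_values)
  r <- relative_range(focal_values)
  f <- sample_size_factor(m, N)
  if (is.na(d) || is.na(r)) {
    dx <- NA_real_; cls <- "undefined"
  } else if (d == 0) {
    dx <- 0; cls <- "none"
  } else if (r == 0) {
    dx <- NA_real_; cls <- "undefined"
  } else {
    dx <- d / (f * r)
    cls <- if (dx > 1) "up" else if (dx < -1) "down" else "none"
  }
  tibble::tibble(d = d, r = r, f = f, delta_x = dx, selection_class = cls)
}

#' Delta-x for every gene of a focal/related expression matrix pair
#'
#' @param focal,related Gene x replicate matrices of log2 TPM values for one
#'   tissue (and typically one sex); restricted to shared genes by row name.
#' @param N Reference sample size (default 3).
#' @return Tibble: `gene_id`, `d`, `r`, `f`, `delta_x`, `selection_class`.
#' @export
delta_x_table <- function(focal, related, N = 3) {
  shared <- intersect(rownames(focal), rownames(related))
  if (length(shared) == 0) stop("no shared genes between focal and related matrices")
  focal <- focal[shared, , drop = FALSE]
  related <- related[shared, , drop = FALSE]
  m <- ncol(focal)
  if (m < 2) stop("relative range needs >= 2 focal replicates")
  mf <- unname(rowMeans(focal))
  mr <- unname(rowMeans(related))
  rng <- unname(apply(focal, 1, max) - apply(focal, 1, min))
  f <- sample_size_factor(m, N)
  d <- ifelse(mf == 0, NA_real_, (mf - mr) / mf)
  r <- ifelse(mf == 0, NA_real_, rng / mf)
  dx <- dplyr::case_when(
    is.na(d) | is.na(r) ~ NA_real_,
    d == 0 ~ 0,
    r == 0 ~ NA_real_,
    TRUE ~ d / (f * r))
  cls <- dplyr::case_when(
    is.na(dx) ~ "undefined",
    dx > 1 ~ "up",
    dx < -1 ~ "down",
    TRUE ~ "none")
  tibble::tibble(gene_id = shared, d = d, r = r, f = f,
                 delta_x = dx, selection_class = cls)
}

#' Run the delta-x analysis from counts, per tissue (and sex)
#'
#' Computes TPM per species, log2-transforms with a pseudocount, and applies
#' [delta_x_table()] within each tissue (by default within each tissue x sex
#' cell, so the focal sample size matches the per-sex replicate count the
#' reference sample size `N` refers to).
#'
#' @param focal_counts,related_counts Count matrices.
#' @param focal_samples,related_samples Sample tibbles.
#' @param annotation Shared gene annotation (for TPM lengths).
#' @param tissue Optional tissue subset (default: all tissues present in
#'   both species).
#' @param by_sex Compute within tissue x sex cells (default `TRUE`).
#' @param pseudocount Pseudocount before log2 (default 1).
#' @param N Reference sample size (default 3).
#' @return Tibble with `tissue` (and `sex`) columns ahead of the
#'   [delta_x_table()] columns.
#' @export
run_dx <- function(focal_counts, focal_samples, related_counts, related_samples,
                   annotation, tissue = NULL, by_sex = TRUE,
                   pseudocount = 1, N = 3) {
  focal_samples <- validate_samples(focal_samples)
  related_samples <- validate_samples(related_samples)
  f_log <- log2_with_pseudocount(tpm(focal_counts, annotation), pseudocount)
  r_log <- log2_with_pseudocount(tpm(related_counts, annotation), pseudocount)
  tissues <- intersect(unique(focal_samples$tissue), unique(related_samples$tissue))
  if (!is.null(tissue)) tissues <- intersect(tissues, tissue)
  if (length(tissues) == 0) stop("no shared tissue between species")
  cells <- if (by_sex) tidyr::expand_grid(tissue = tissues, sex = c("female", "male"))
           else tibble::tibble(tissue = tissues)
  purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    tt <- cells$tissue[i]
    fs <- focal_samples$tissue == tt
    rs <- related_samples$tissue == tt
    if (by_sex) {
      fs <- fs & focal_samples$sex == cells$sex[i]
      rs <- rs & related_samples$sex == cells$sex[i]
    }
    if (sum(fs) < 2 || sum(rs) < 1) return(NULL)
    out <- delta_x_table(f_log[, focal_samples$sample_id[fs], drop = FALSE],
                         r_log[, related_samples$sample_id[rs], drop = FALSE],
                         N = N)
    out$tissue <- tt
    if (by_sex) out$sex <- cells$sex[i]
    dplyr::relocate(out, dplyr::any_of(c("tissue", "sex")), .after = "gene_id")
  })
}

#' Fisher test for excess directional selection in a gene category
#'
#' Cross-tabulates selection status (|delta_x| > 1 vs not) against a binary
#' gene category and applies a two-sided Fisher exact test, per tissue when
#' a `tissue` column is present, plus a pooled row. Genes with class
#' "undefined" are excluded from both cells by default.
#'
#' @param dx Tibble from [delta_x_table()] / [run_dx()] (needs `gene_id`,
#'   `selection_class`, optionally `tissue`).
#' @param categories Tibble `(gene_id, category)` with exactly two category
#'   levels (e.g. SBG vs unbiased, sex_chromosome vs autosome, FBG vs MBG).
#' @param undefined `"exclude"` (default) or `"not_selected"` - policy for
#'   genes with undefined delta-x.
#' @return Tibble per tissue (and pooled): counts, selection proportions per
#'   category, `odds_ratio`, `fisher_p`.
#' @export
selection_enrichment <- function(dx, categories,
                                 undefined = c("exclude", "not_selected")) {
  undefined <- match.arg(undefined)
  lv <- sort(unique(categories$category))
  if (length(lv) != 2) stop("categories must have exactly two levels, got: ",
                            paste(lv, collapse = ", "))
  tab <- dplyr::inner_join(tibble::as_tibble(dx), categories, by = "gene_id")
  if (undefined == "exclude") tab <- tab[tab$selection_class != "undefined", ]
  tab$selected <- tab$selection_class %in% c("up", "down")

  one <- function(df, label) {
    n1 <- sum(df$category == lv[1]); n2 <- sum(df$category == lv[2])
    if (n1 == 0 || n2 == 0)
      return(tibble::tibble(tissue = label, category_1 = lv[1], category_2 = lv[2],
                            n_1 = n1, n_2 = n2, sel_1 = NA_integer_, sel_2 = NA_integer_,
                            prop_1 = NA_real_, prop_2 = NA_real_,
                            odds_ratio = NA_real_, fisher_p = NA_real_))
    s1 <- sum(df$selected & df$category == lv[1])
    s2 <- sum(df$selected & df$category == lv[2])
    ft <- stats::fisher.test(matrix(c(s1, n1 - s1, s2, n2 - s2), nrow = 2),
                             alternative = "two.sided")
    tibble::tibble(tissue = label, category_1 = lv[1], category_2 = lv[2],
                   n_1 = n1, n_2 = n2, sel_1 = s1, sel_2 = s2,
                   prop_1 = s1 / n1, prop_2 = s2 / n2,
                   odds_ratio = unname(ft$estimate), fisher_p = ft$p.value)
  }
  if ("tissue" %in% names(tab)) {
    per <- purrr::map_dfr(split(tab, tab$tissue), function(df) one(df, df$tissue[1]))
    dplyr::bind_rows(per, one(tab, "pooled"))
  } else {
    one(tab, "pooled")
  }
}
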