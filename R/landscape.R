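#' Classify genes into sex-chromosome / autosome / excluded
#'
#' Mitochondrial genes and genes on unplaced scaffolds are excluded from all
#' sex-chromosome-vs-autosome contrasts. A species with unknown heterogamety
#' yields no sex-chromosome labels (it cannot enter such contrasts).
#'
#' @param annotation Gene annotation tibble (see [read_annotation()]).
#' @param sex_systems Sex-system tibble (see [read_sex_systems()]).
#' @param species Species whose sex-linked chromosomes apply.
#' @return Tibble `(gene_id, chromosome, chrom_class)` with `chrom_class` in
#'   `sex_chromosome`, `autosome`, `excluded`.
#' @export
classify_chromosomes <- function(annotation, sex_systems, species) {
  row <- sex_systems[sex_systems$species == species, ]
  if (nrow(row) != 1)
    stop("species '", species, "' not found (exactly once) in the sex-system table")
  sex_linked <- row$sex_linked_chromosomes[[1]]
  missing_chr <- setdiff(sex_linked, unique(annotation$chromosome))
  if (length(missing_chr) > 0)
    stop("declared sex-linked chromosome(s) absent from annotation: ",
         paste(missing_chr, collapse = ", "))
  tibble::tibble(
    gene_id = annotation$gene_id,
    chromosome = annotation$chromosome,
    chrom_class = dplyr::case_when(
      annotation$is_mitochondrial | !annotation$is_placed ~ "excluded",
      annotation$chromosome %in% sex_linked ~ "sex_chromosome",
      TRUE ~ "autosome"))
}

# genes of a DE table joined to classing, excluded dropped, NA class dropped
landscape_universe <- function(de, classing) {
  tab <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(de), dplyr::any_of(c("gene_id", "lfc", "padj", "bias_class"))),
    classing, by = "gene_id")
  missing <- setdiff(de$gene_id, classing$gene_id)
  if (length(missing) > 0)
    stop("classing does not cover tested gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  tab[tab$chrom_class != "excluded" & !is.na(tab$bias_class), , drop = FALSE]
}

#' Per-chromosome sex-biased gene counts and proportions
#'
#' Denominator: expressed (tested, non-excluded) genes per chromosome.
#'
#' @param de DE result tibble with `gene_id` and `bias_class`.
#' @param classing Result of [classify_chromosomes()].
#' @return Tibble per chromosome: `n_expressed`, `n_fbg`, `n_mbg`, `n_sbg`,
#'   `prop_fbg`, `prop_mbg`, `prop_sbg`, `chrom_class`.
#' @export
sbg_proportions <- function(de, classing) {
  tab <- landscape_universe(de, classing)
  out <- tab |>
    dplyr::group_by(.data$chromosome, .data$chrom_class) |>
    dplyr::summarise(
      n_expressed = dplyr::n(),
      n_fbg = sum(.data$bias_class == "FBG"),
      n_mbg = sum(.data$bias_class == "MBG"),
      .groups = "drop") |>
    dplyr::mutate(
      n_sbg = .data$n_fbg + .data$n_mbg,
      prop_fbg = ifelse(.data$n_expressed > 0, .data$n_fbg / .data$n_expressed, NA_real_),
      prop_mbg = ifelse(.data$n_expressed > 0, .data$n_mbg / .data$n_expressed, NA_real_),
      prop_sbg = ifelse(.data$n_expressed > 0, .data$n_sbg / .data$n_expressed, NA_real_)) |>
    dplyr::arrange(.data$chromosome)
  out
}

fisher_2x2 <- function(a, b, c, d, chromosome) {
  tab <- matrix(c(a, b, c, d), nrow = 2,
                dimnames = list(sbg = c("yes", "no"),
                                location = c("on_chromosome", "autosome")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  tibble::tibble(
    chromosome = chromosome,
    sbg_on = a, nonsbg_on = b, sbg_auto = c, nonsbg_auto = d,
    odds_ratio = unname(ft$estimate),
    fisher_p = ft$p.value,
    direction = dplyr::case_when(
      a + b == 0 | c + d == 0 | a + c == 0 | b + d == 0 ~ "degenerate",
      unname(ft$estimate) > 1 ~ "enriched",
      unname(ft$estimate) < 1 ~ "depleted",
      TRUE ~ "none"))
}

#' Fisher enrichment of sex-biased genes on a chromosome
#'
#' Two-sided Fisher exact test on the 2x2 table (SBG vs non-SBG) x (on the
#' chromosome vs on autosomes). The autosomal background excludes the focal
#' chromosome, every other sex chromosome and all excluded genes.
#'
#' @param de DE result tibble.
#' @param classing Result of [classify_chromosomes()].
#' @param chromosome Focal chromosome name.
#' @param bias `"all"` (any SBG, default), `"FBG"` or `"MBG"`.
#' @return One-row tibble: table cells, `odds_ratio`, `fisher_p`,
#'   `direction`.
#' @export
enrichment_fisher <- function(de, classing, chromosome, bias = c("all", "FBG", "MBG")) {
  bias <- match.arg(bias)
  tab <- landscape_universe(de, classing)
  on_chr <- tab$chromosome == chromosome
  on_auto <- tab$chrom_class == "autosome" & tab$chromosome != chromosome
  is_sbg <- if (bias == "all") tab$bias_class %in% c("FBG", "MBG")
            else tab$bias_class == bias
  fisher_2x2(sum(on_chr & is_sbg), sum(on_chr & !is_sbg),
             sum(on_auto & is_sbg), sum(on_auto & !is_sbg), chromosome)
}

#' Fisher test on cross-species sharing of sex-biased genes
#'
#' Restricts to genes tested in both species, flags genes carrying the given
#' bias in both, and tests whether shared-bias genes are over-represented on
#' the chromosome relative to autosomes (two-sided Fisher exact test).
#'
#' @param de_a,de_b DE result tibbles for the two species.
#' @param classing Result of [classify_chromosomes()] on the shared
#'   annotation.
#' @param chromosome Focal chromosome.
#' @param bias `"FBG"` or `"MBG"`.
#' @return One-row tibble as in [enrichment_fisher()].
#' @export
shared_sbg_fisher <- function(de_a, de_b, classing, chromosome,
                              bias = c("FBG", "MBG")) {
  bias <- match.arg(bias)
  a <- landscape_universe(de_a, classing)
  b <- landscape_universe(de_b, classing)
  shared <- dplyr::inner_join(
    dplyr::select(a, "gene_id", "chromosome", "chrom_class", bias_a = "bias_class"),
    dplyr::select(b, "gene_id", bias_b = "bias_class"), by = "gene_id")
  if (nrow(shared) == 0) stop("no genes tested in both species")
  on_chr <- shared$chromosome == chromosome
  on_auto <- shared$chrom_class == "autosome" & shared$chromosome != chromosome
  both <- shared$bias_a == bias & shared$bias_b == bias
  fisher_2x2(sum(on_chr & both), sum(on_chr & !both),
             sum(on_auto & both), sum(on_auto & !both), chromosome)
}

#' Rank tests on sex-bias intensity between chromosome groups
#'
#' Compares the log2 fold changes (or their absolute values) of sex-biased
#' genes between chromosome groups: Wilcoxon-Mann-Whitney for two groups,
#' Kruskal-Wallis for three or more.
#'
#' @param de DE result tibble.
#' @param classing Result of [classify_chromosomes()].
#' @param groups Named list mapping group name to a character vector of
#'   chromosome names, or `NULL` entries meaning "all autosomes". Default:
#'   declared sex chromosome(s) vs autosomes via `chrom_class`.
#' @param absolute Use |LFC| instead of signed LFC (default `FALSE`).
#' @param sbg_only Restrict to classified SBGs (default `TRUE`).
#' @return One-row tibble: `test`, `statistic`, `p_value`, and group sizes
#'   in a list column `group_n`.
#' @export
lfc_distribution_tests <- function(de, classing, groups = NULL,
                                   absolute = FALSE, sbg_only = TRUE) {
  tab <- landscape_universe(de, classing)
  if (sbg_only) tab <- tab[tab$bias_class %in% c("FBG", "MBG"), ]
  if (is.null(groups)) {
    values <- split(tab$lfc, tab$chrom_class)
    values <- values[intersect(c("sex_chromosome", "autosome"), names(values))]
  } else {
    values <- lapply(groups, function(chr) {
      if (is.null(chr)) tab$lfc[tab$chrom_class == "autosome"]
      else tab$lfc[tab$chromosome %in% chr]
    })
  }
  if (length(values) < 2) stop("need at least two chromosome groups")
  if (any(vapply(values, length, 1L) < 2))
    stop("each group needs >= 2 sex-biased genes")
  if (absolute) values <- lapply(values, abs)
  if (length(values) == 2) {
    ht <- stats::wilcox.test(values[[1]], values[[2]], exact = FALSE)
    test <- "wilcoxon"
  } else {
    ht <- stats::kruskal.test(values)
    test <- "kruskal-wallis"
  }
  tibble::tibble(test = test, statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 group_n = list(vapply(values, length, 1L)))
}

#' Feminisation / masculinisation summary by chromosome group
#'
#' Per chromosome group (sex chromosome vs autosome): median LFC of SBGs
#' (negative = feminised), mean |LFC| of FBGs and of MBGs, and the FBG:MBG
#' count ratio, with group sizes. Groups without SBGs report `NA` metrics.
#'
#' @param de DE result tibble.
#' @param classing Result of [classify_chromosomes()].
#' @param by `"chrom_class"` (default) or `"chromosome"`.
#' @return Tibble with one row per group.
#' @export
feminisation_summary <- function(de, classing, by = c("chrom_class", "chromosome")) {
  by <- match.arg(by)
  tab <- landscape_universe(de, classing)
  summarise_group <- function(lfc, bias) {
    fbg <- lfc[bias == "FBG"]; mbg <- lfc[bias == "MBG"]
    sbg <- lfc[bias %in% c("FBG", "MBG")]
    tibble::tibble(
      n_expressed = length(lfc),
      n_fbg = length(fbg), n_mbg = length(mbg), n_sbg = length(sbg),
      median_lfc_sbg = if (length(sbg) > 0) stats::median(sbg) else NA_real_,
      mean_abs_lfc_fbg = if (length(fbg) > 0) mean(abs(fbg)) else NA_real_,
      mean_abs_lfc_mbg = if (length(mbg) > 0) mean(abs(mbg)) else NA_real_,
      fbg_mbg_ratio = if (length(mbg) > 0) length(fbg) / length(mbg) else NA_real_)
  }
  tab |>
    dplyr::group_by(group = .data[[by]]) |>
    dplyr::reframe(summarise_group(.data$lfc, .data$bias_class))
}
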