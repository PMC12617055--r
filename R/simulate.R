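#' Simulate a multi-species, two-sex, multi-tissue RNA-seq count dataset
#'
#' Draws negative-binomial counts (`var = mu + alpha * mu^2`) for every gene
#' and sample implied by the configuration, together with the sample table,
#' a gene annotation (chromosome, coordinates, length, mitochondrial and
#' placement flags) and the ground truth needed for recovery testing.
#'
#' The per-gene log2 mean is `baseline + tissue effect + sign(sex) * lfc/2`,
#' where the sign is +1 for males and -1 for females, so the male/female
#' log2 ratio of means equals the recorded true LFC. Each sample gets a
#' multiplicative library-size factor. Each species consumes its own RNG
#' stream derived from the master seed (sub-seeds drawn once, in species
#' order), so adding a species leaves existing species' data unchanged.
#' Gene lengths and coordinates are drawn once and shared across species.
#'
#' @param config A [sim_config()].
#' @return A list of class `sbg_sim` with elements:
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples (all species).}
#'     \item{samples}{tibble `(sample_id, species, sex, tissue, replicate)`.}
#'     \item{annotation}{tibble `(gene_id, chromosome, start, end, length,
#'       is_mitochondrial, is_placed)`; 0-based half-open coordinates.}
#'     \item{truth}{list with `effects` tibble `(species, gene_id, tissue,
#'       true_lfc, true_bias_class)` and `size_factors` tibble
#'       `(sample_id, size_factor)`.}
#'     \item{config}{the input configuration.}
#'   }
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 200, seed = 42))
#' dim(sim$counts)
#' @export
simulate_dataset <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  annotation <- draw_annotation(config)
  baseline <- stats::rnorm(config$n_genes, config$baseline_log_mean,
                           config$baseline_log_sd)
  tissue_eff <- matrix(stats::rnorm(config$n_genes * length(config$tissues),
                                    0, config$tissue_effect_sd),
                       nrow = config$n_genes,
                       dimnames = list(annotation$gene_id, config$tissues))
  n_sp <- nrow(config$species_specs)
  species_seeds <- sample.int(.Machine$integer.max - 1L, n_sp)

  per_species <- lapply(seq_len(n_sp), function(i) {
    spec <- config$species_specs[i, ]
    set.seed(species_seeds[i])
    simulate_one_species(config, spec, annotation, baseline, tissue_eff)
  })

  counts <- do.call(cbind, lapply(per_species, `[[`, "counts"))
  samples <- dplyr::bind_rows(lapply(per_species, `[[`, "samples"))
  effects <- dplyr::bind_rows(lapply(per_species, `[[`, "effects"))
  size_factors <- dplyr::bind_rows(lapply(per_species, `[[`, "size_factors"))

  structure(list(counts = counts, samples = samples, annotation = annotation,
                 truth = list(effects = effects, size_factors = size_factors),
                 config = config),
            class = "sbg_sim")
}

# Gene ids, chromosome assignment in table order, lengths, 0-based coordinates.
draw_annotation <- function(config) {
  n <- config$n_genes
  gene_id <- sprintf("gene%05d", seq_len(n))
  chromosome <- rep(config$chromosomes$name, config$chromosomes$gene_count)
  length_bp <- round(stats::runif(n, config$gene_length_range[1],
                                  config$gene_length_range[2]))
  # lay genes head-to-tail with a fixed intergenic gap per contig
  start <- unlist(lapply(split(length_bp, factor(chromosome, levels = config$chromosomes$name)),
                         function(l) cumsum(c(0, l[-length(l)] + 1000L))),
                  use.names = FALSE)
  tibble::tibble(
    gene_id = gene_id, chromosome = chromosome,
    start = start, end = start + length_bp, length = length_bp,
    is_mitochondrial = chromosome == "MT",
    is_placed = chromosome != "unplaced"
  )
}

# Draw sex-effect truth and counts for one species; assumes the species RNG
# stream has been seeded by the caller.
simulate_one_species <- function(config, spec, annotation, baseline, tissue_eff) {
  n <- config$n_genes
  sex_linked <- spec$sex_linked_chromosomes[[1]]
  on_sexchrom <- annotation$chromosome %in% sex_linked
  sbg_prob <- ifelse(on_sexchrom, config$sbg_fraction_sexchrom,
                     config$sbg_fraction_autosome)
  is_sbg <- stats::runif(n) < sbg_prob
  p_female <- ifelse(on_sexchrom,
                     switch(spec$sex_system,
                            ZW = config$female_bias_prob_sexchrom,
                            XY = 1 - config$female_bias_prob_sexchrom,
                            unknown = 0.5),
                     0.5)
  female_biased <- stats::runif(n) < p_female
  magnitude <- abs(stats::rnorm(n, config$lfc_mean, config$lfc_sd))
  lfc <- ifelse(is_sbg, ifelse(female_biased, -magnitude, magnitude), 0)

  tissues <- config$tissues
  reps <- config$replicates_per_sex
  grid <- expand.grid(replicate = seq_len(reps), sex = c("female", "male"),
                      tissue = tissues, stringsAsFactors = FALSE)
  sample_id <- sprintf("%s_%s_%s_r%d", spec$species, grid$tissue, grid$sex,
                       grid$replicate)
  lsr <- log(config$library_size_spread)
  size_factor <- exp(stats::runif(nrow(grid), lsr[1], lsr[2]))

  counts <- matrix(0L, nrow = n, ncol = nrow(grid),
                   dimnames = list(annotation$gene_id, sample_id))
  size <- 1 / config$dispersion
  for (j in seq_len(nrow(grid))) {
    s <- if (grid$sex[j] == "male") 1 else -1
    mu <- size_factor[j] * 2^(baseline + tissue_eff[, grid$tissue[j]] + s * lfc / 2)
    counts[, j] <- stats::rnbinom(n, mu = mu, size = size)
  }
  storage.mode(counts) <- "integer"

  effects <- tidyr::expand_grid(species = spec$species,
                                gene_id = annotation$gene_id,
                                tissue = tissues)
  effects$true_lfc <- rep(lfc, each = length(tissues))
  effects$true_bias_class <- dplyr::case_when(
    effects$true_lfc < 0 ~ "FBG",
    effects$true_lfc > 0 ~ "MBG",
    TRUE ~ "unbiased"
  )

  list(counts = counts,
       samples = tibble::tibble(sample_id = sample_id, species = spec$species,
                                sex = grid$sex, tissue = grid$tissue,
                                replicate = grid$replicate),
       effects = effects,
       size_factors = tibble::tibble(sample_id = sample_id,
                                     size_factor = size_factor))
}

#' Simulate a focal/related species pair for expression-divergence analysis
#'
#' The related species is drawn from the shared baseline; the focal species
#' from baseline plus a per-gene divergence shift. A configurable fraction of
#' genes receives a shift of `outgroup_shift_magnitude` log2 units with a
#' random sign, applied in every tissue and both sexes. Sex-biased effects
#' are drawn as in [simulate_dataset()] (identically in both species, from
#' the shared stream, so the pair shares its true SBGs).
#'
#' @param config A [sim_config()]; the first row of `species_specs` provides
#'   the sex system used for the shared sex-bias truth.
#' @param shift_fraction_biased Optional probability that a true SBG receives
#'   a divergence shift; unbiased genes then use
#'   `config$outgroup_shift_fraction`. `NULL` (default) applies
#'   `outgroup_shift_fraction` to all genes alike.
#' @param sbg_shared_fraction Probability that a focal SBG keeps its sex
#'   effect in the related species (default 1 = fully shared truth); genes
#'   not shared are unbiased in the related species.
#' @param focal_name,related_name Species labels for the emitted tables.
#' @return List of class `sbg_sim_pair`: `focal` and `related` (each with
#'   `counts` and `samples`), shared `annotation`, and `truth` containing
#'   `effects` (per-species sex-bias truth), `shifts` tibble
#'   `(gene_id, tissue, true_shift)` and per-sample `size_factors`.
#' @export
simulate_species_pair_for_dx <- function(config, shift_fraction_biased = NULL,
                                         sbg_shared_fraction = 1,
                                         focal_name = "focal",
                                         related_name = "related") {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  annotation <- draw_annotation(config)
  baseline <- stats::rnorm(config$n_genes, config$baseline_log_mean,
                           config$baseline_log_sd)
  tissue_eff <- matrix(stats::rnorm(config$n_genes * length(config$tissues),
                                    0, config$tissue_effect_sd),
                       nrow = config$n_genes,
                       dimnames = list(annotation$gene_id, config$tissues))
  spec <- config$species_specs[1, ]

  # shared sex-bias truth (same stream -> same SBGs in both species)
  n <- config$n_genes
  sex_linked <- spec$sex_linked_chromosomes[[1]]
  on_sexchrom <- annotation$chromosome %in% sex_linked
  sbg_prob <- ifelse(on_sexchrom, config$sbg_fraction_sexchrom,
                     config$sbg_fraction_autosome)
  is_sbg <- stats::runif(n) < sbg_prob
  p_female <- ifelse(on_sexchrom,
                     switch(spec$sex_system,
                            ZW = config$female_bias_prob_sexchrom,
                            XY = 1 - config$female_bias_prob_sexchrom,
                            unknown = 0.5),
                     0.5)
  female_biased <- stats::runif(n) < p_female
  magnitude <- abs(stats::rnorm(n, config$lfc_mean, config$lfc_sd))
  lfc <- ifelse(is_sbg, ifelse(female_biased, -magnitude, magnitude), 0)

  shared <- stats::runif(n) < sbg_shared_fraction
  lfc_related <- ifelse(shared, lfc, 0)

  shift_prob <- if (is.null(shift_fraction_biased)) {
    rep(config$outgroup_shift_fraction, n)
  } else {
    ifelse(lfc != 0, shift_fraction_biased, config$outgroup_shift_fraction)
  }
  shifted <- stats::runif(n) < shift_prob
  shift_sign <- ifelse(stats::runif(n) < 0.5, -1, 1)
  shift <- ifelse(shifted, shift_sign * config$outgroup_shift_magnitude, 0)

  draw_species <- function(name, extra_shift, lfc) {
    tissues <- config$tissues
    reps <- config$replicates_per_sex
    grid <- expand.grid(replicate = seq_len(reps), sex = c("female", "male"),
                        tissue = tissues, stringsAsFactors = FALSE)
    sample_id <- sprintf("%s_%s_%s_r%d", name, grid$tissue, grid$sex,
                         grid$replicate)
    lsr <- log(config$library_size_spread)
    size_factor <- exp(stats::runif(nrow(grid), lsr[1], lsr[2]))
    counts <- matrix(0L, nrow = n, ncol = nrow(grid),
                     dimnames = list(annotation$gene_id, sample_id))
    size <- 1 / config$dispersion
    for (j in seq_len(nrow(grid))) {
      s <- if (grid$sex[j] == "male") 1 else -1
      mu <- size_factor[j] *
        2^(baseline + tissue_eff[, grid$tissue[j]] + s * lfc / 2 + extra_shift)
      counts[, j] <- stats::rnbinom(n, mu = mu, size = size)
    }
    storage.mode(counts) <- "integer"
    list(counts = counts,
         samples = tibble::tibble(sample_id = sample_id, species = name,
                                  sex = grid$sex, tissue = grid$tissue,
                                  replicate = grid$replicate),
         size_factors = tibble::tibble(sample_id = sample_id,
                                       size_factor = size_factor))
  }

  related <- draw_species(related_name, 0, lfc_related)
  focal <- draw_species(focal_name, shift, lfc)

  truth_effects <- function(name, lfc) {
    eff <- tidyr::expand_grid(species = name, gene_id = annotation$gene_id,
                              tissue = config$tissues)
    eff$true_lfc <- rep(lfc, each = length(config$tissues))
    eff$true_bias_class <- dplyr::case_when(
      eff$true_lfc < 0 ~ "FBG",
      eff$true_lfc > 0 ~ "MBG",
      TRUE ~ "unbiased")
    eff
  }
  effects <- dplyr::bind_rows(truth_effects(focal_name, lfc),
                              truth_effects(related_name, lfc_related))
  shifts <- tidyr::expand_grid(gene_id = annotation$gene_id,
                               tissue = config$tissues)
  shifts$true_shift <- rep(shift, each = length(config$tissues))

  structure(list(
    focal = focal[c("counts", "samples")],
    related = related[c("counts", "samples")],
    annotation = annotation,
    truth = list(effects = effects, shifts = shifts,
                 size_factors = dplyr::bind_rows(focal$size_factors,
                                                 related$size_factors))),
    class = "sbg_sim_pair")
}

#' @export
print.sbg_sim <- function(x, ...) {
  cat(sprintf("<sbg_sim> %d genes x %d samples, %d species\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$species))))
  invisible(x)
}
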