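#' Chromosome layout for a simulated genome
#'
#' Builds the `chromosomes` table of a [sim_config()]: `n_lg` linkage groups
#' sharing the placed genes, a mitochondrial contig, and a block of unplaced
#' scaffold genes. Defaults emulate a cichlid-style reference with 22 linkage
#' groups.
#'
#' @param n_genes Total number of genes across all contigs.
#' @param n_lg Number of linkage groups (autosomes + sex chromosomes).
#' @param mito_genes Genes on the mitochondrial contig.
#' @param unplaced_frac Fraction of genes on unplaced scaffolds.
#' @return A tibble with columns `name` and `gene_count` summing to `n_genes`.
#' @export
default_chromosomes <- function(n_genes, n_lg = 22, mito_genes = 13,
                                unplaced_frac = 0.04) {
  stopifnot(n_genes > n_lg + mito_genes)
  n_unplaced <- floor(n_genes * unplaced_frac)
  n_placed <- n_genes - mito_genes - n_unplaced
  per_lg <- rep(n_placed %/% n_lg, n_lg)
  extra <- n_placed - sum(per_lg)
  if (extra > 0) per_lg[seq_len(extra)] <- per_lg[seq_len(extra)] + 1L
  tibble::tibble(
    name = c(sprintf("LG%02d", seq_len(n_lg)), "MT", "unplaced"),
    gene_count = c(per_lg, mito_genes, n_unplaced)
  )
}

#' Species declaration for the simulator
#'
#' @param species Species name.
#' @param sex_system One of `"XY"`, `"ZW"`, `"unknown"`.
#' @param sex_linked_chromosomes Character vector of sex-linked chromosome
#'   names; must be empty when `sex_system = "unknown"`.
#' @return A one-row tibble (`sex_linked_chromosomes` is a list column).
#' @export
species_spec <- function(species, sex_system = c("ZW", "XY", "unknown"),
                         sex_linked_chromosomes = character()) {
  sex_system <- match.arg(sex_system)
  if (sex_system == "unknown" && length(sex_linked_chromosomes) > 0)
    stop("species with unknown sex system must not declare sex-linked chromosomes")
  tibble::tibble(
    species = species,
    sex_system = sex_system,
    sex_linked_chromosomes = list(as.character(sex_linked_chromosomes))
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic RNA-seq generator. The defaults emulate the
#' design the package targets: per species, five tissues (gonad, brain,
#' gills, liver, lower pharyngeal jaw) x two sexes x three replicates, genes
#' spread over 22 linkage groups plus a mitochondrial contig and unplaced
#' scaffolds, with a higher fraction of sex-biased genes on the declared sex
#' chromosome(s) than on autosomes.
#'
#' Counts are negative-binomial with `var = mu + dispersion * mu^2`. The sex
#' effect is injected symmetrically (+lfc/2 in males, -lfc/2 in females) so
#' the male/female log2 ratio of means equals the recorded true LFC and the
#' overall expression level is orthogonal to bias. Negative true LFC means
#' female-biased, positive male-biased.
#'
#' @param n_genes Number of genes (shared across species; orthology by id).
#' @param chromosomes Tibble `(name, gene_count)`; defaults to
#'   [default_chromosomes()]. Gene counts must sum to `n_genes`.
#' @param species_specs Tibble from [species_spec()] rows (one per species).
#' @param tissues Character vector of tissue names.
#' @param replicates_per_sex Replicates per sex per tissue (>= 2).
#' @param baseline_log_mean,baseline_log_sd Per-gene baseline log2 mean
#'   expression: Normal(mean, sd) on the log2 scale.
#' @param tissue_effect_sd SD (log2) of per-gene, per-tissue effects.
#' @param dispersion NB dispersion alpha (> 0), common to all genes.
#' @param sbg_fraction_autosome,sbg_fraction_sexchrom Per-gene probability of
#'   a nonzero sex effect on autosomes / sex chromosomes.
#' @param female_bias_prob_sexchrom Probability that a sex-chromosome SBG is
#'   female-biased in a ZW species (> 0.5 emulates feminisation); XY species
#'   use `1 - female_bias_prob_sexchrom` (masculinisation). Autosomal SBGs
#'   are female-biased with probability 0.5.
#' @param lfc_mean,lfc_sd Magnitude of true |LFC| (log2): `abs(Normal(mean, sd))`.
#' @param library_size_spread Length-2 range of per-sample multiplicative
#'   library-size factors (drawn log-uniform).
#' @param gene_length_range Length-2 range (bp) of gene lengths (uniform,
#'   shared across species).
#' @param outgroup_shift_fraction Fraction of genes given a focal-vs-related
#'   divergence shift in [simulate_species_pair_for_dx()].
#' @param outgroup_shift_magnitude Magnitude (log2) of that shift.
#' @param seed Integer seed; identical configs give identical outputs.
#' @return A validated object of class `sim_config` (a list).
#' @export
sim_config <- function(n_genes = 2000,
                       chromosomes = default_chromosomes(n_genes),
                       species_specs = species_spec("speciesA", "ZW", "LG05"),
                       tissues = c("gonad", "brain", "gills", "liver",
                                   "lower_pharyngeal_jaw"),
                       replicates_per_sex = 3,
                       baseline_log_mean = 5,
                       baseline_log_sd = 2,
                       tissue_effect_sd = 2,
                       dispersion = 0.1,
                       sbg_fraction_autosome = 0.02,
                       sbg_fraction_sexchrom = 0.10,
                       female_bias_prob_sexchrom = 0.8,
                       lfc_mean = 2,
                       lfc_sd = 0.5,
                       library_size_spread = c(0.5, 2),
                       gene_length_range = c(300, 10000),
                       outgroup_shift_fraction = 0,
                       outgroup_shift_magnitude = 2,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), chromosomes = tibble::as_tibble(chromosomes),
    species_specs = tibble::as_tibble(species_specs), tissues = as.character(tissues),
    replicates_per_sex = as.integer(replicates_per_sex),
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    tissue_effect_sd = tissue_effect_sd, dispersion = dispersion,
    sbg_fraction_autosome = sbg_fraction_autosome,
    sbg_fraction_sexchrom = sbg_fraction_sexchrom,
    female_bias_prob_sexchrom = female_bias_prob_sexchrom,
    lfc_mean = lfc_mean, lfc_sd = lfc_sd,
    library_size_spread = as.numeric(library_size_spread),
    gene_length_range = as.numeric(gene_length_range),
    outgroup_shift_fraction = outgroup_shift_fraction,
    outgroup_shift_magnitude = outgroup_shift_magnitude,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  props <- c("sbg_fraction_autosome", "sbg_fraction_sexchrom",
             "female_bias_prob_sexchrom", "outgroup_shift_fraction")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a proportion in [0, 1], got %s", p, format(v)))
  }
  if (!is.numeric(cfg$dispersion) || cfg$dispersion <= 0)
    stop("'dispersion' must be > 0")
  if (cfg$replicates_per_sex < 2)
    stop("'replicates_per_sex' must be >= 2 (the relative range r needs >= 2 replicates)")
  if (sum(cfg$chromosomes$gene_count) != cfg$n_genes)
    stop(sprintf("chromosome gene counts sum to %d but n_genes = %d",
                 sum(cfg$chromosomes$gene_count), cfg$n_genes))
  if (anyDuplicated(cfg$chromosomes$name))
    stop("duplicate chromosome names")
  if (anyDuplicated(cfg$species_specs$species))
    stop("duplicate species names in species_specs")
  for (i in seq_len(nrow(cfg$species_specs))) {
    sl <- cfg$species_specs$sex_linked_chromosomes[[i]]
    missing_chr <- setdiff(sl, cfg$chromosomes$name)
    if (length(missing_chr) > 0)
      stop(sprintf("sex-linked chromosome(s) %s of species '%s' absent from chromosome table",
                   paste(missing_chr, collapse = ", "),
                   cfg$species_specs$species[i]))
  }
  if (length(cfg$library_size_spread) != 2 || any(cfg$library_size_spread <= 0))
    stop("'library_size_spread' must be two positive numbers")
  if (length(cfg$gene_length_range) != 2 || cfg$gene_length_range[1] <= 0)
    stop("'gene_length_range' must be two positive lengths (bp)")
  if (length(cfg$tissues) < 1) stop("at least one tissue required")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d genes on %d contigs | %d species | %d tissues x 2 sexes x %d replicates | alpha = %g, seed = %d\n",
    x$n_genes, nrow(x$chromosomes), nrow(x$species_specs),
    length(x$tissues), x$replicates_per_sex, x$dispersion, x$seed))
  invisible(x)
}
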