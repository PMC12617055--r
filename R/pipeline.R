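run_config_defaults <- list(
  alpha = 0.05, pseudocount = 1, stepsize = "auto",
  min_count = 5, min_samples_exclusive = 3,
  dx_pairs = list(), rrho_pairs = list(), out_dir = NULL, seed = 1L)

run_config_keys <- c(names(run_config_defaults),
                     c("simulate", "input", "sex_systems", "species"))

#' Validate a pipeline configuration
#'
#' Accepts a YAML or JSON file path, or a plain list. Exactly one of
#' `simulate` (a list of [sim_config()] arguments) or `input` (paths
#' `counts`, `samples`, `annotation`) must be given; `sex_systems` is a list
#' of per-species entries `(species, heterogamety, sex_linked_chromosomes)`
#' or a TSV path. Unknown keys are errors in strict mode, warnings
#' otherwise. All collected errors are reported together, each naming the
#' offending key.
#'
#' @param config File path or list.
#' @param strict Error on unknown keys (default `TRUE`).
#' @return A validated `run_config` list with defaults filled.
#' @export
validate_config <- function(config, strict = TRUE) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  errors <- character(0)
  unknown <- setdiff(names(config), run_config_keys)
  if (length(unknown) > 0) {
    msg <- paste0("unknown config key(s): ", paste(unknown, collapse = ", "),
                  " - remove or check spelling")
    if (strict) errors <- c(errors, msg) else warning(msg)
  }
  has_sim <- !is.null(config$simulate)
  has_input <- !is.null(config$input)
  if (has_sim == has_input)
    errors <- c(errors, "exactly one of 'simulate' or 'input' must be provided")
  if (has_input) {
    for (k in c("counts", "samples", "annotation")) {
      if (is.null(config$input[[k]]))
        errors <- c(errors, paste0("input$", k, ": path required"))
      else if (!file.exists(config$input[[k]]))
        errors <- c(errors, paste0("input$", k, ": file not found: ", config$input[[k]]))
    }
  }
  for (k in names(run_config_defaults))
    if (is.null(config[[k]])) config[[k]] <- run_config_defaults[[k]]
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1)
    errors <- c(errors, "alpha: must lie in (0, 1)")
  if (!identical(config$stepsize, "auto") &&
      (!is.numeric(config$stepsize) || config$stepsize < 1))
    errors <- c(errors, "stepsize: 'auto' or a positive integer")
  pair_ok <- function(p) length(p) == 2 && p[[1]] != p[[2]]
  for (nm in c("dx_pairs", "rrho_pairs")) {
    bad <- !vapply(config[[nm]], pair_ok, TRUE)
    if (any(bad))
      errors <- c(errors, paste0(nm, ": each pair must name two distinct species"))
  }
  if (length(errors) > 0)
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  class(config) <- "run_config"
  config
}

#' Run the full pipeline
#'
#' Simulates or loads a dataset, then per species runs the tissue-combined
#' and tissue-specific differential-expression analyses, the chromosome
#' landscape (proportions, enrichment per declared sex chromosome,
#' feminisation metrics), delta-x tables plus selection-enrichment tests
#' for the configured focal/related pairs, and RRHO maps with BY correction
#' and concordance summaries for the configured species pairs. Failures are
#' isolated per species/stage and collected in the summary.
#'
#' @param config A `run_config` (see [validate_config()]) or anything it
#'   accepts.
#' @return List of class `sbg_run`: `data` (counts/samples/annotation),
#'   `de` (per species: `combined`, `per_tissue`), `landscape`, `dx`,
#'   `rrho`, `summary` (flat, machine-readable), `errors` (named character
#'   vector of isolated stage failures). When `out_dir` is set, all tables
#'   plus `summary.json` are written there.
#' @export
run_full <- function(config) {
  config <- validate_config(config)
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    if (!is.null(sim_args$species_specs) && is.data.frame(sim_args$species_specs) == FALSE)
      sim_args$species_specs <- dplyr::bind_rows(lapply(sim_args$species_specs, function(s)
        species_spec(s$species, s$sex_system, unlist(s$sex_linked_chromosomes))))
    dat <- do.call(sim_config, sim_args) |> simulate_dataset()
    counts <- dat$counts; samples <- dat$samples; annotation <- dat$annotation
    sex_systems <- tibble::tibble(
      species = dat$config$species_specs$species,
      heterogamety = dat$config$species_specs$sex_system,
      sex_linked_chromosomes = dat$config$species_specs$sex_linked_chromosomes)
    truth <- dat$truth
  } else {
    counts <- read_counts(config$input$counts)
    samples <- read_samples(config$input$samples, counts)
    annotation <- read_annotation(config$input$annotation, counts = counts)
    sex_systems <- if (is.character(config$sex_systems)) read_sex_systems(config$sex_systems)
      else validate_sex_systems(dplyr::bind_rows(lapply(config$sex_systems, function(s)
        tibble::tibble(species = s$species, heterogamety = s$heterogamety,
                       sex_linked_chromosomes = list(unlist(s$sex_linked_chromosomes))))))
    truth <- NULL
  }
  species <- config$species %||% unique(samples$species)
  errors <- character(0)
  note_error <- function(stage, e) {
    errors[[stage]] <<- conditionMessage(e)
    NULL
  }

  de <- lapply(stats::setNames(species, species), function(sp) {
    list(
      combined = tryCatch(
        run_de(counts, samples, sp, model = "tissue_combined", alpha = config$alpha,
               min_count = config$min_count,
               min_samples_exclusive = config$min_samples_exclusive),
        error = function(e) note_error(paste0("de_combined:", sp), e)),
      per_tissue = tryCatch(
        run_de(counts, samples, sp, model = "tissue_specific", alpha = config$alpha,
               min_count = config$min_count,
               min_samples_exclusive = config$min_samples_exclusive),
        error = function(e) note_error(paste0("de_per_tissue:", sp), e)))
  })

  landscape <- lapply(stats::setNames(species, species), function(sp) {
    d <- de[[sp]]$combined
    if (is.null(d) || !(sp %in% sex_systems$species)) return(NULL)
    tryCatch({
      cls <- classify_chromosomes(annotation, sex_systems, sp)
      sex_chroms <- sex_systems$sex_linked_chromosomes[[match(sp, sex_systems$species)]]
      list(classing = cls,
           proportions = sbg_proportions(d, cls),
           enrichment = purrr::map_dfr(sex_chroms, function(chr)
             enrichment_fisher(d, cls, chr)),
           feminisation = feminisation_summary(d, cls))
    }, error = function(e) note_error(paste0("landscape:", sp), e))
  })

  dx <- lapply(config$dx_pairs, function(pair) {
    focal <- pair[[1]]; related <- pair[[2]]
    tryCatch({
      fs <- samples[samples$species == focal, ]
      rs <- samples[samples$species == related, ]
      dx_tab <- run_dx(counts[, fs$sample_id, drop = FALSE], fs,
                       counts[, rs$sample_id, drop = FALSE], rs,
                       annotation, pseudocount = config$pseudocount)
      enr <- NULL
      d <- de[[focal]]$combined
      if (!is.null(d)) {
        cats <- tibble::tibble(
          gene_id = d$gene_id,
          category = ifelse(d$bias_class %in% c("FBG", "MBG"), "SBG", "unbiased"))
        cats <- cats[!is.na(d$bias_class), ]
        enr <- selection_enrichment(dx_tab, cats)
      }
      list(focal = focal, related = related, table = dx_tab, enrichment = enr)
    }, error = function(e) note_error(paste0("dx:", focal, "_vs_", related), e))
  })

  rrho <- lapply(config$rrho_pairs, function(pair) {
    a <- pair[[1]]; b <- pair[[2]]
    tryCatch({
      da <- de[[a]]$combined; db <- de[[b]]$combined
      if (is.null(da) || is.null(db)) stop("missing DE result for RRHO pair")
      pa <- compute_dde(da); pb <- compute_dde(db)
      step <- if (identical(config$stepsize, "auto")) NULL else config$stepsize
      map <- adjust_by(rrho_map(pa, pb, stepsize = step))
      list(species = c(a, b), map = map,
           concordance = concordance_summary(pa, pb),
           quadrants = rrho_quadrant_summary(map))
    }, error = function(e) note_error(paste0("rrho:", a, "_vs_", b), e))
  })

  summary <- pipeline_summary(species, de, landscape, dx, rrho, config)
  run <- structure(list(
    data = list(counts = counts, samples = samples, annotation = annotation,
                sex_systems = sex_systems, truth = truth),
    de = de, landscape = landscape, dx = dx, rrho = rrho,
    summary = summary, errors = errors, config = config),
    class = "sbg_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

pipeline_summary <- function(species, de, landscape, dx, rrho, config) {
  per_species <- lapply(stats::setNames(species, species), function(sp) {
    d <- de[[sp]]$combined
    if (is.null(d)) return(NULL)
    s <- list(n_tested = sum(!is.na(d$bias_class)),
              n_fbg = sum(d$bias_class == "FBG", na.rm = TRUE),
              n_mbg = sum(d$bias_class == "MBG", na.rm = TRUE))
    s$prop_sbg <- (s$n_fbg + s$n_mbg) / s$n_tested
    ls <- landscape[[sp]]
    if (!is.null(ls) && nrow(ls$enrichment) > 0) {
      s$sex_chrom_enrichment_p <- stats::setNames(as.list(ls$enrichment$fisher_p),
                                                  ls$enrichment$chromosome)
      fem <- ls$feminisation
      i <- match("sex_chromosome", fem$group)
      if (!is.na(i)) s$median_lfc_sbg_sexchrom <- fem$median_lfc_sbg[i]
    }
    s
  })
  dx_summary <- lapply(dx, function(x) {
    if (is.null(x)) return(NULL)
    pooled <- x$enrichment[x$enrichment$tissue == "pooled", ]
    list(pair = paste(x$focal, "vs", x$related),
         prop_selected_sbg = if (nrow(pooled) > 0) pooled$prop_1 else NA,
         prop_selected_unbiased = if (nrow(pooled) > 0) pooled$prop_2 else NA,
         fisher_p = if (nrow(pooled) > 0) pooled$fisher_p else NA)
  })
  rrho_summary <- lapply(rrho, function(x) {
    if (is.null(x)) return(NULL)
    list(pair = paste(x$species, collapse = " vs "),
         proportion_concordant = x$concordance$proportion_concordant,
         spearman_rho = x$concordance$spearman_rho)
  })
  list(species = per_species, dx = dx_summary, rrho = rrho_summary,
       alpha = config$alpha, seed = config$seed)
}

write_run <- function(run, out_dir) {
  tables <- list()
  for (sp in names(run$de)) {
    if (!is.null(run$de[[sp]]$combined))
      tables[[paste0("de_combined_", sp)]] <- run$de[[sp]]$combined
    if (!is.null(run$de[[sp]]$per_tissue))
      tables[[paste0("de_per_tissue_", sp)]] <- run$de[[sp]]$per_tissue
    ls <- run$landscape[[sp]]
    if (!is.null(ls)) {
      tables[[paste0("sbg_proportions_", sp)]] <- ls$proportions
      tables[[paste0("enrichment_", sp)]] <- ls$enrichment
      tables[[paste0("feminisation_", sp)]] <- ls$feminisation
    }
  }
  for (x in run$dx) {
    if (is.null(x)) next
    key <- paste0("dx_", x$focal, "_vs_", x$related)
    tables[[key]] <- x$table
    if (!is.null(x$enrichment)) tables[[paste0(key, "_enrichment")]] <- x$enrichment
  }
  for (x in run$rrho) {
    if (is.null(x)) next
    key <- paste0("rrho_", paste(x$species, collapse = "_vs_"))
    tables[[key]] <- tidy(x$map)
    tables[[paste0(key, "_concordance")]] <- x$concordance
  }
  files <- write_results(tables, out_dir,
                         meta = c(run$summary,
                                  list(errors = as.list(run$errors))))
  invisible(files)
}

#' @export
print.sbg_run <- function(x, ...) {
  cat(sprintf("<sbg_run> %d species | %d genes x %d samples | %d stage error(s)\n",
              length(x$de), nrow(x$data$counts), ncol(x$data$counts),
              length(x$errors)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
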