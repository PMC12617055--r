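test_that("config validation enforces proportions, dispersion, replicates and chromosome sums", {
  expect_error(sim_config(sbg_fraction_autosome = 1.2), "proportion")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(replicates_per_sex = 1), "replicates_per_sex")
  expect_error(sim_config(n_genes = 100,
                          chromosomes = tibble::tibble(name = "LG01", gene_count = 99)),
               "sum")
  expect_error(sim_config(species_specs = species_spec("x", "ZW", "LG99")),
               "absent")
  expect_error(species_spec("x", "unknown", "LG05"), "unknown")
})

test_that("the study design yields 2 sexes x replicates x tissues sample columns per species", {
  sim <- simulate_dataset(sim_config(n_genes = 120, seed = 1))
  expect_equal(ncol(sim$counts), 5 * 2 * 3)   # five tissues, three replicates per sex
  expect_equal(nrow(sim$counts), 120)
  expect_setequal(unique(sim$samples$sex), c("male", "female"))
  expect_equal(sort(unique(sim$samples$tissue)),
               sort(c("gonad", "brain", "gills", "liver", "lower_pharyngeal_jaw")))
  expect_true(all(sim$annotation$length == sim$annotation$end - sim$annotation$start))
  expect_true(all(sim$annotation$is_mitochondrial == (sim$annotation$chromosome == "MT")))
})

test_that("identical configs give identical outputs; different seeds differ", {
  cfg <- sim_config(n_genes = 150, seed = 99)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  c <- simulate_dataset(sim_config(n_genes = 150, seed = 100))
  expect_false(identical(a$counts, c$counts))
})

test_that("adding a species leaves existing species' data unchanged", {
  two <- dplyr::bind_rows(species_spec("sp1", "ZW", "LG05"),
                          species_spec("sp2", "XY", "LG15"))
  a <- simulate_dataset(sim_config(n_genes = 150, seed = 5,
                                   species_specs = species_spec("sp1", "ZW", "LG05")))
  ab <- simulate_dataset(sim_config(n_genes = 150, seed = 5,
                                    species_specs = two))
  sp1_cols <- ab$samples$sample_id[ab$samples$species == "sp1"]
  expect_identical(a$counts[, colnames(a$counts)], ab$counts[, sp1_cols])
})

test_that("null configuration produces no sex effects", {
  sim <- simulate_dataset(sim_config(n_genes = 100, seed = 2,
                                     sbg_fraction_autosome = 0,
                                     sbg_fraction_sexchrom = 0))
  expect_true(all(sim$truth$effects$true_lfc == 0))
  expect_true(all(sim$truth$effects$true_bias_class == "unbiased"))
})

test_that("bias-class truth follows the sign convention", {
  sim <- tiny_sim(n_genes = 500)
  eff <- sim$truth$effects
  expect_true(all(eff$true_bias_class[eff$true_lfc < 0] == "FBG"))
  expect_true(all(eff$true_bias_class[eff$true_lfc > 0] == "MBG"))
  expect_true(all(eff$true_bias_class[eff$true_lfc == 0] == "unbiased"))
})

test_that("counts follow the NB mean-variance relation var = mu + alpha mu^2", {
  cfg <- sim_config(n_genes = 2000, dispersion = 0.1, seed = 7,
                    tissues = "gonad", replicates_per_sex = 30,
                    sbg_fraction_autosome = 0, sbg_fraction_sexchrom = 0,
                    library_size_spread = c(1, 1), tissue_effect_sd = 0)
  sim <- simulate_dataset(cfg)
  m <- rowMeans(sim$counts)
  v <- apply(sim$counts, 1, var)
  keep <- m > 50    # moment check needs decent counts
  alpha_hat <- (v[keep] - m[keep]) / m[keep]^2
  expect_gt(sum(keep), 500)
  expect_equal(median(alpha_hat), 0.1, tolerance = 0.15)
})

test_that("realised SBG fractions converge to the configured fractions per chromosome class", {
  cfg <- sim_config(n_genes = 5000, seed = 11, sbg_fraction_autosome = 0.02,
                    sbg_fraction_sexchrom = 0.10)
  sim <- simulate_dataset(cfg)
  per_gene <- dplyr::distinct(sim$truth$effects, gene_id, true_bias_class)
  per_gene <- dplyr::left_join(per_gene, sim$annotation, by = "gene_id")
  on_sex <- per_gene$chromosome == "LG05"
  frac_sex <- mean(per_gene$true_bias_class[on_sex] != "unbiased")
  frac_auto <- mean(per_gene$true_bias_class[!on_sex] != "unbiased")
  # binomial 3 SE tolerances
  expect_lt(abs(frac_sex - 0.10), 3 * sqrt(0.1 * 0.9 / sum(on_sex)))
  expect_lt(abs(frac_auto - 0.02), 3 * sqrt(0.02 * 0.98 / sum(!on_sex)))
})

test_that("ZW feminisation probability controls the sign of sex-chromosome SBGs", {
  cfg <- sim_config(n_genes = 8000, seed = 13, sbg_fraction_sexchrom = 0.5,
                    female_bias_prob_sexchrom = 0.8)
  sim <- simulate_dataset(cfg)
  per_gene <- dplyr::distinct(sim$truth$effects, gene_id, true_bias_class)
  per_gene <- dplyr::left_join(per_gene, sim$annotation, by = "gene_id")
  sbg_sex <- per_gene[per_gene$chromosome == "LG05" &
                        per_gene$true_bias_class != "unbiased", ]
  frac_female <- mean(sbg_sex$true_bias_class == "FBG")
  expect_equal(frac_female, 0.8, tolerance = 0.1)
})

test_that("species pair: no shift centres delta-x at zero, a large shift drives it past 1", {
  base <- list(n_genes = 400, seed = 21, tissues = "brain", dispersion = 0.01,
               sbg_fraction_autosome = 0, sbg_fraction_sexchrom = 0,
               outgroup_shift_magnitude = 2)
  # no divergence at all: delta-x centred at zero
  cfg0 <- do.call(sim_config, c(base, list(outgroup_shift_fraction = 0)))
  pair0 <- simulate_species_pair_for_dx(cfg0)
  dx0 <- run_dx(pair0$focal$counts, pair0$focal$samples,
                pair0$related$counts, pair0$related$samples,
                pair0$annotation, by_sex = FALSE)
  expect_lt(abs(median(dx0$delta_x, na.rm = TRUE)), 0.15)

  # +2 log2 shifts push delta-x past 1 for almost all shifted genes
  cfg <- do.call(sim_config, c(base, list(outgroup_shift_fraction = 0.3)))
  pair <- simulate_species_pair_for_dx(cfg)
  dx <- run_dx(pair$focal$counts, pair$focal$samples,
               pair$related$counts, pair$related$samples,
               pair$annotation, by_sex = FALSE)
  shift <- dplyr::distinct(pair$truth$shifts, gene_id, true_shift)
  j <- dplyr::inner_join(dx, shift, by = "gene_id")
  expect_gt(mean(j$delta_x[j$true_shift > 0] > 1, na.rm = TRUE), 0.9)

  # determinism of the pair generator
  pair2 <- simulate_species_pair_for_dx(cfg)
  expect_identical(pair$focal$counts, pair2$focal$counts)
  expect_identical(pair$related$counts, pair2$related$counts)
})

test_that("partial SBG sharing is reflected in the related species' truth", {
  cfg <- sim_config(n_genes = 4000, seed = 31, tissues = "brain",
                    sbg_fraction_autosome = 0.2, sbg_fraction_sexchrom = 0.2)
  pair <- simulate_species_pair_for_dx(cfg, sbg_shared_fraction = 0.7)
  eff <- dplyr::distinct(pair$truth$effects, species, gene_id, true_lfc)
  wide <- tidyr::pivot_wider(eff, names_from = species, values_from = true_lfc)
  sbg_focal <- wide$focal != 0
  shared <- mean(wide$related[sbg_focal] != 0)
  expect_equal(shared, 0.7, tolerance = 0.08)
  # shared genes keep the identical effect
  keep <- sbg_focal & wide$related != 0
  expect_identical(wide$focal[keep], wide$related[keep])
})
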