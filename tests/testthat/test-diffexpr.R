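test_that("the Wald test matches the standard normal and is sign-symmetric", {
  expect_equal(wald_test(0, 1), 1)
  expect_equal(wald_test(1.959964, 1), 0.05, tolerance = 1e-6)
  expect_equal(wald_test(2.3, 1.7), wald_test(-2.3, 1.7))
  expect_warning(p0 <- wald_test(1, 0), "zero standard error")
  expect_equal(p0, 0)
})

test_that("BH adjustment matches the hand computation and excludes NA from the family", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  p <- c(0.01, NA, 0.04)
  out <- adjust_bh(p)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], stats::p.adjust(c(0.01, 0.04), "BH"))
  p <- runif(50)
  expect_true(all(adjust_bh(p) >= p))
  expect_error(adjust_bh(c(0.5, 2)), "0, 1")
})

test_that("near-Poisson two-group fits match the closed-form log-ratio of normalized means", {
  set.seed(42)
  X <- stats::model.matrix(~ sex, data.frame(sex = factor(rep(c("female", "male"), each = 3),
                                                          levels = c("female", "male"))))
  sf <- c(1, 1.4, 0.8, 1, 1.2, 0.9)
  for (i in 1:20) {
    y <- c(rpois(3, 40), rpois(3, 90)) * 1L
    # Poisson MLE with offsets: rate ratio of size-factor-weighted group means
    fit <- fit_nb_glm(y, sf, X, alpha_g = 1e-12)
    closed <- log2((sum(y[4:6]) / sum(sf[4:6])) / (sum(y[1:3]) / sum(sf[1:3])))
    expect_equal(unname(fit$coefficients["sexmale"]), closed, tolerance = 1e-6)
    # with unit size factors this is the log-ratio of normalized group means
    fit1 <- fit_nb_glm(y, rep(1, 6), X, alpha_g = 1e-12)
    expect_equal(unname(fit1$coefficients["sexmale"]),
                 log2(mean(y[4:6]) / mean(y[1:3])), tolerance = 1e-6)
  }
})

test_that("identical groups give zero LFC and doubling size factors changes nothing", {
  X <- stats::model.matrix(~ sex, data.frame(sex = factor(rep(c("female", "male"), each = 3),
                                                          levels = c("female", "male"))))
  y <- c(7L, 7L, 7L, 7L, 7L, 7L)
  sf <- rep(1, 6)
  fit <- fit_nb_glm(y, sf, X, 0.1)
  expect_equal(unname(fit$coefficients["sexmale"]), 0, tolerance = 1e-10)
  y2 <- c(12L, 9L, 15L, 30L, 25L, 41L)
  f1 <- fit_nb_glm(y2, sf, X, 0.1)
  f2 <- fit_nb_glm(y2, 2 * sf, X, 0.1)
  expect_equal(f1$coefficients["sexmale"], f2$coefficients["sexmale"], tolerance = 1e-8)
  expect_equal(f1$se, f2$se, tolerance = 1e-8)
})

test_that("gene-wise moment dispersion recovers Poisson and NB truths", {
  set.seed(31)
  # Poisson: estimates land at (or near) the floor for most genes
  cm <- matrix(rpois(500 * 30, 100), 500, 30,
               dimnames = list(paste0("g", 1:500), paste0("s", 1:30)))
  design <- data.frame(group = factor(rep(c("a", "b"), each = 15)))
  a_hat <- estimate_dispersion(cm, rep(1, 30), design, method = "gene-wise")
  expect_lt(median(a_hat), 0.01)

  # NB alpha = 0.2: median within +-50%
  cm2 <- matrix(rnbinom(500 * 30, mu = 100, size = 5), 500, 30,
                dimnames = dimnames(cm))
  a2 <- estimate_dispersion(cm2, rep(1, 30), design, method = "gene-wise")
  expect_gt(median(a2), 0.1)
  expect_lt(median(a2), 0.3)
  # trend pools the same information across genes
  a2t <- estimate_dispersion(cm2, rep(1, 30), design, method = "trend")
  expect_equal(mean(a2t), 0.2, tolerance = 0.25)

  # constant counts -> floor
  cm3 <- matrix(50L, 30, 30, dimnames = list(paste0("g", 1:30), paste0("s", 1:30)))
  a3 <- estimate_dispersion(cm3, rep(1, 30), design, method = "gene-wise")
  expect_true(all(a3 == 1e-8))

  # singleton cells fall back with a warning
  d1 <- data.frame(group = factor(c(rep("a", 29), "b")))
  expect_warning(estimate_dispersion(cm, rep(1, 30), d1, method = "gene-wise"),
                 "< 2 replicates")
})

test_that("run_de validates its design preconditions", {
  sim <- tiny_sim(seed = 12)
  males <- sim$samples[sim$samples$sex == "male", ]
  expect_error(run_de(sim$counts, males, "speciesA"), "both sexes")
  gonad <- sim$samples[sim$samples$tissue == "gonad", ]
  expect_error(run_de(sim$counts[, gonad$sample_id], gonad, "speciesA",
                      model = "tissue_combined"), "tissue_specific")
  expect_error(run_de(sim$counts, sim$samples, "nope"), "no samples")
})

test_that("run_de recovers strong injected sex effects with correct signs", {
  sim <- simulate_dataset(sim_config(n_genes = 500, seed = 23,
                                     tissues = c("gonad", "brain", "liver"),
                                     sbg_fraction_autosome = 0.1,
                                     sbg_fraction_sexchrom = 0.1,
                                     lfc_mean = 2, lfc_sd = 0))
  de <- run_de(sim$counts, sim$samples, "speciesA")
  truth <- dplyr::distinct(sim$truth$effects, gene_id, true_bias_class)
  j <- dplyr::inner_join(tidy(de), truth, by = "gene_id")
  j <- j[!is.na(j$bias_class), ]

  injected <- j[j$true_bias_class != "unbiased", ]
  expect_gt(mean(injected$bias_class == injected$true_bias_class), 0.8)
  # no sign flips among classified SBGs
  called <- injected[injected$bias_class %in% c("FBG", "MBG"), ]
  expect_true(all(called$bias_class == called$true_bias_class))
  # classification partitions the tested genes
  expect_true(all(j$bias_class %in% c("FBG", "MBG", "unbiased")))
  # estimated LFC tracks the injected magnitude
  expect_equal(median(abs(called$lfc)), 2, tolerance = 0.35)
})

test_that("tissue-specific runs reuse the species-level gene set and label tissues", {
  sim <- tiny_sim(seed = 29, n_genes = 200, tissues = c("gonad", "brain"))
  de_all <- run_de(sim$counts, sim$samples, "speciesA", model = "tissue_specific")
  expect_setequal(unique(de_all$tissue), c("gonad", "brain"))
  de_comb <- run_de(sim$counts, sim$samples, "speciesA")
  expect_setequal(unique(de_all$gene_id), de_comb$gene_id)
  de_one <- run_de(sim$counts, sim$samples, "speciesA",
                   model = "tissue_specific", tissue = "gonad")
  expect_equal(de_one, de_all[de_all$tissue == "gonad", ], ignore_attr = TRUE)
})

test_that("results agree with an independent DESeq2 fit on a strongly biased simulation", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_dataset(sim_config(n_genes = 200, seed = 37,
                                     tissues = c("gonad", "brain"),
                                     sbg_fraction_autosome = 0.2,
                                     sbg_fraction_sexchrom = 0.2, lfc_sd = 0))
  cm <- filter_low_counts(sim$counts)
  cd <- data.frame(sex = factor(sim$samples$sex, c("female", "male")),
                   tissue = factor(sim$samples$tissue))
  dds <- DESeq2::DESeqDataSetFromMatrix(cm, cd, ~ tissue + sex)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds, contrast = c("sex", "male", "female"))
  de <- run_de(sim$counts, sim$samples, "speciesA")
  j <- dplyr::inner_join(tidy(de),
                         tibble::tibble(gene_id = rownames(res),
                                        lfc_ref = res$log2FoldChange,
                                        padj_ref = res$padj),
                         by = "gene_id")
  expect_gt(cor(j$lfc, j$lfc_ref, use = "complete.obs"), 0.95)
  both_called <- (j$padj < 0.05) & (j$padj_ref < 0.05)
  agree <- sign(j$lfc[both_called]) == sign(j$lfc_ref[both_called])
  expect_true(all(agree, na.rm = TRUE))
})

test_that("glance and tidy summarise a DE result", {
  sim <- tiny_sim(seed = 41, n_genes = 150)
  de <- run_de(sim$counts, sim$samples, "speciesA")
  g <- glance(de)
  expect_equal(g$n_tested, sum(!is.na(de$padj)))
  expect_equal(g$n_fbg + g$n_mbg, sum(de$bias_class %in% c("FBG", "MBG")))
  expect_s3_class(tidy(de), "tbl_df")
  expect_null(attr(tidy(de), "species"))
})
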