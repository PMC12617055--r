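toy_classing <- function() {
  ann <- tibble::tibble(
    gene_id = c(paste0("x", 1:10), paste0("a", 1:100), "mt1", "un1"),
    chromosome = c(rep("LG_X", 10), rep(c("LG01", "LG02"), 50), "MT", "scaffold_1"),
    start = 0, end = 1000, length = 1000,
    is_mitochondrial = c(rep(FALSE, 110), TRUE, FALSE),
    is_placed = c(rep(TRUE, 111), FALSE))
  ss <- dplyr::bind_rows(species_spec("zw", "ZW", "LG_X"),
                         species_spec("unk", "unknown"))
  classify_chromosomes(ann, ss, "zw")
}

toy_de <- function(mbg_x = 4, mbg_auto = 5) {
  cls <- toy_classing()
  ids <- cls$gene_id
  lfc <- rep(0.1, length(ids))
  padj <- rep(0.9, length(ids))
  mbg <- c(paste0("x", seq_len(mbg_x)), paste0("a", seq_len(mbg_auto)))
  padj[ids %in% mbg] <- 0.001
  tibble::tibble(gene_id = ids, lfc = lfc, pvalue = padj / 2, padj = padj,
                 bias_class = ifelse(padj < 0.05, "MBG", "unbiased"))
}

test_that("chromosome classification labels sex chromosomes and exclusions", {
  cls <- toy_classing()
  expect_true(all(cls$chrom_class[grepl("^x", cls$gene_id)] == "sex_chromosome"))
  expect_true(all(cls$chrom_class[grepl("^a", cls$gene_id)] == "autosome"))
  expect_equal(cls$chrom_class[cls$gene_id %in% c("mt1", "un1")],
               c("excluded", "excluded"))

  ann <- tibble::tibble(gene_id = "g", chromosome = "LG01", start = 0, end = 10,
                        length = 10, is_mitochondrial = FALSE, is_placed = TRUE)
  ss <- dplyr::bind_rows(species_spec("zw", "ZW", "LG_X"),
                         species_spec("unk", "unknown"))
  expect_error(classify_chromosomes(ann, ss, "zw"), "absent")
  expect_error(classify_chromosomes(ann, ss, "missing"), "not found")
  # unknown system yields no sex-chromosome labels
  cls_unk <- classify_chromosomes(tibble::add_row(ann, gene_id = "h", chromosome = "LG02",
                                                  start = 0, end = 10, length = 10,
                                                  is_mitochondrial = FALSE, is_placed = TRUE),
                                  ss, "unk")
  expect_true(all(cls_unk$chrom_class != "sex_chromosome"))
})

test_that("per-chromosome SBG proportions use expressed genes as denominator", {
  props <- sbg_proportions(toy_de(), toy_classing())
  x <- props[props$chromosome == "LG_X", ]
  expect_equal(x$prop_mbg, 0.40)
  expect_equal(x$n_expressed, 10)
  autos <- props[props$chrom_class == "autosome", ]
  expect_equal(sum(autos$n_mbg) / sum(autos$n_expressed), 0.05)
  expect_equal(props$prop_fbg + props$prop_mbg, props$prop_sbg)
  expect_false("MT" %in% props$chromosome)

  de0 <- toy_de(0, 0)
  props0 <- sbg_proportions(de0, toy_classing())
  expect_true(all(props0$prop_sbg == 0))
})

test_that("Fisher enrichment matches the enumeration oracle and its invariances", {
  de <- toy_de()
  cls <- toy_classing()
  enr <- enrichment_fisher(de, cls, "LG_X")
  expect_equal(enr$sbg_on, 4); expect_equal(enr$nonsbg_on, 6)
  expect_equal(enr$sbg_auto, 5); expect_equal(enr$nonsbg_auto, 95)
  expect_equal(enr$fisher_p, oracle_fisher_p(4, 6, 5, 95), tolerance = 1e-12)
  expect_equal(enr$direction, "enriched")

  # a skewed reference table, against enumeration
  ft <- stats::fisher.test(matrix(c(8, 2, 10, 40), 2))
  expect_equal(ft$p.value, oracle_fisher_p(8, 2, 10, 40), tolerance = 1e-12)

  # symmetric toy: equal rates give p = 1
  ft1 <- stats::fisher.test(matrix(c(5, 45, 5, 45), 2))
  expect_equal(ft1$p.value, 1)

  # doubling all cells preserves the direction of the odds ratio estimate
  f_small <- stats::fisher.test(matrix(c(8, 2, 10, 40), 2))$estimate
  f_big <- stats::fisher.test(matrix(c(16, 4, 20, 80), 2))$estimate
  expect_equal(sign(log(f_small)), sign(log(f_big)))
})

test_that("shared-SBG Fisher reduces to plain enrichment when both species are identical", {
  de <- toy_de()
  de$bias_class[de$bias_class == "MBG"] <- "FBG"
  de$lfc[de$bias_class == "FBG"] <- -1
  cls <- toy_classing()
  shared <- shared_sbg_fisher(de, de, cls, "LG_X", bias = "FBG")
  plain <- enrichment_fisher(de, cls, "LG_X", bias = "FBG")
  expect_equal(shared$fisher_p, plain$fisher_p)
  expect_equal(shared$sbg_on, plain$sbg_on)

  # no SBGs anywhere -> degenerate margins, p = 1
  de0 <- toy_de(0, 0)
  s0 <- shared_sbg_fisher(de0, de0, cls, "LG_X", bias = "FBG")
  expect_equal(s0$fisher_p, 1)
  expect_equal(s0$direction, "degenerate")
})

test_that("rank tests on LFC distributions behave like their stats oracles", {
  cls <- toy_classing()
  de <- toy_de(10, 50)
  set.seed(4)
  vals <- rnorm(10, 1, 0.2)
  # sex-chromosome and autosomal SBGs carry the same LFC multiset
  de$lfc[de$bias_class == "MBG" & grepl("^x", de$gene_id)] <- vals
  de$lfc[de$bias_class == "MBG" & grepl("^a", de$gene_id)] <- rep(vals, 5)
  same <- lfc_distribution_tests(de, cls)
  expect_gt(same$p_value, 0.9)

  # strong location shift is detected
  de2 <- de
  sel <- de2$bias_class == "MBG" & grepl("^x", de2$gene_id)
  de2$lfc[sel] <- de2$lfc[sel] + 2
  shift <- lfc_distribution_tests(de2, cls)
  expect_lt(shift$p_value, 0.001)

  # Kruskal-Wallis on two tie-free groups matches Wilcoxon (normal approx.)
  g1 <- rnorm(15); g2 <- rnorm(40)
  kw <- stats::kruskal.test(list(g1, g2))$p.value
  wc <- stats::wilcox.test(g1, g2, exact = FALSE, correct = FALSE)$p.value
  expect_equal(kw, wc, tolerance = 1e-10)

  expect_error(lfc_distribution_tests(de, cls, groups = list(a = "LG_X")),
               "two chromosome groups")
})

test_that("feminisation metrics recover simulated ZW feminisation and ignore gene order", {
  sim <- simulate_dataset(sim_config(n_genes = 600, seed = 19,
                                     tissues = c("gonad", "brain"),
                                     sbg_fraction_sexchrom = 0.5,
                                     sbg_fraction_autosome = 0.05,
                                     female_bias_prob_sexchrom = 0.85))
  de <- run_de(sim$counts, sim$samples, "speciesA")
  ss <- tibble::tibble(species = "speciesA", heterogamety = "ZW",
                       sex_linked_chromosomes = list("LG05"))
  cls <- classify_chromosomes(sim$annotation, ss, "speciesA")
  fem <- feminisation_summary(de, cls)
  sx <- fem[fem$group == "sex_chromosome", ]
  expect_lt(sx$median_lfc_sbg, 0)
  expect_gt(sx$fbg_mbg_ratio, 1)

  shuffled <- de[sample(nrow(de)), ]
  fem2 <- feminisation_summary(shuffled, cls)
  expect_equal(dplyr::arrange(fem, group), dplyr::arrange(fem2, group))

  # all-male-biased toy: medians positive everywhere
  de_m <- toy_de()
  de_m$lfc[de_m$bias_class == "MBG"] <- 1.5
  fem3 <- feminisation_summary(de_m, toy_classing())
  expect_true(all(fem3$median_lfc_sbg > 0, na.rm = TRUE))
})
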