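test_that("simulated genotypes follow the binomial dosage model", {
  cfg <- sim_config(n_individuals = 400, n_snps = 50, maf_range = c(0.5, 0.5),
                    seed = 1)
  g <- simulate_genotypes(cfg)
  se <- sqrt(2 * 0.5 * 0.5 / 400)
  expect_true(all(abs(colMeans(g$dosages) - 1) < 3 * se + 0.05))

  cfg2 <- sim_config(n_individuals = 2000, n_snps = 30, maf_range = c(0.2, 0.2),
                     seed = 2)
  g2 <- simulate_genotypes(cfg2)
  v <- apply(g2$dosages, 2, var)
  expect_true(all(abs(v - 0.32) / 0.32 < 0.10))

  # determinism and layout
  g3 <- simulate_genotypes(cfg2)
  expect_identical(g2$dosages, g3$dosages)
  expect_equal(length(unique(g2$chromosomes)), min(18L, 30L))
  expect_error(sim_config(10, 10, maf_range = c(0, 0.6)), "maf_range")
})

test_that("annotation class assignment is multinomial and conserving", {
  cfg <- sim_config(n_individuals = 5, n_snps = 10000,
                    class_proportions = c(protein_coding = 0.45, ncRNA = 0.05,
                                          intergenic = 0.50), seed = 3)
  g <- simulate_genotypes(cfg)
  al <- assign_annotation_classes(cfg, g)
  expect_equal(sum(lengths(al$members)), 10000L)
  expect_lt(abs(length(al$members$protein_coding) - 4500),
            3 * sqrt(10000 * 0.45 * 0.55))
  # degenerate proportions put every SNP in one class
  cfg1 <- sim_config(5, 100, class_proportions = c(protein_coding = 1), seed = 3)
  al1 <- assign_annotation_classes(cfg1, simulate_genotypes(cfg1))
  expect_identical(al1$members$protein_coding, 1:100)
})

test_that("trait simulation hits QTL counts, disjointness, and heritability", {
  cfg <- sim_config(n_individuals = 200, n_snps = 3000, seed = 11)
  g <- simulate_genotypes(cfg)
  al <- assign_annotation_classes(cfg, g)
  sim <- simulate_traits(cfg, g, al)
  expect_length(sim$truth$qtl_enriched, 500L)
  expect_length(sim$truth$qtl_genomewide, 20L)
  expect_length(intersect(sim$truth$qtl_enriched, sim$truth$qtl_genomewide), 0L)
  expect_true(all(sim$truth$qtl_enriched %in% al$members$protein_coding))
  # pleiotropic effect correlation near the configured 0.5 at 520 QTL
  expect_equal(cor(sim$truth$effects)[1, 2], 0.5, tolerance = 0.1)

  # heritability calibration on a larger sample
  cfg2 <- sim_config(n_individuals = 5000, n_snps = 400, n_qtl_enriched = 40,
                     n_qtl_genomewide = 5, heritabilities = 0.5, seed = 13)
  g2 <- simulate_genotypes(cfg2)
  al2 <- assign_annotation_classes(cfg2, g2)
  sim2 <- simulate_traits(cfg2, g2, al2)
  ratio <- var(sim2$truth$breeding_values[, 1]) / var(sim2$phenotypes$values[, 1])
  expect_equal(ratio, 0.5, tolerance = 0.03)

  # h2 = 1 means phenotype equals the true breeding value
  cfg3 <- sim_config(n_individuals = 50, n_snps = 200, n_qtl_enriched = 10,
                     n_qtl_genomewide = 2, heritabilities = 1, seed = 7)
  g3 <- simulate_genotypes(cfg3)
  al3 <- assign_annotation_classes(cfg3, g3)
  sim3 <- simulate_traits(cfg3, g3, al3)
  expect_equal(unname(sim3$phenotypes$values[, 1]),
               unname(sim3$truth$breeding_values[, 1]))

  # reproducible QTL sets under a fixed seed
  sim4 <- simulate_traits(cfg, g, al)
  expect_identical(sim4$truth$qtl_idx, sim$truth$qtl_idx)

  cfg_small <- sim_config(n_individuals = 20, n_snps = 50, n_qtl_enriched = 45,
                          heritabilities = 0.5, seed = 1)
  g_small <- simulate_genotypes(cfg_small)
  al_small <- assign_annotation_classes(cfg_small, g_small)
  expect_error(simulate_traits(cfg_small, g_small, al_small), "QTL requested")
})
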