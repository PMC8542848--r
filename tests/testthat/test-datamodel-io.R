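test_that("genotype CSV parsing enforces the dosage coding", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,s1,s2", "a,0,2", "b,1,1", "c,2,0"), tmp)
  g <- read_genotypes(tmp)
  expect_equal(dim(g), c(3L, 2L))
  expect_identical(g$snp_ids, c("s1", "s2"))
  expect_identical(g$individual_ids, c("a", "b", "c"))

  writeLines(c("id,s1,s2", "a,0,2", "b,3,1"), tmp)
  expect_error(read_genotypes(tmp), "dosage not in \\{0,1,2,NA\\}.*s1")

  writeLines(c("id,s1,s1", "a,0,2"), tmp)
  expect_error(read_genotypes(tmp), "duplicate SNP id")
})

test_that("write -> read round trip reproduces a simulated matrix exactly", {
  g <- simulate_genotypes(sim_config(n_individuals = 50, n_snps = 200, seed = 5))
  tmp <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".map")
  write_genotypes(g, tmp, map = mp)
  g2 <- read_genotypes(tmp, map = mp)
  expect_identical(unname(g2$dosages), unname(g$dosages))
  expect_identical(g2$snp_ids, g$snp_ids)
  expect_identical(g2$chromosomes, g$chromosomes)
  expect_identical(g2$positions, g$positions)
  expect_identical(g2$individual_ids, g$individual_ids)
})

test_that("PLINK text pairs are converted to minor-allele dosage", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- sub("\\.ped$", ".map", ped)
  # s1: alleles A (rare) / G; s2 has a missing genotype for ind2
  writeLines(c("f1 ind1 0 0 1 -9 A G C C",
               "f2 ind2 0 0 2 -9 G G 0 0",
               "f3 ind3 0 0 1 -9 A A C T"), ped)
  writeLines(c("1\ts1\t0\t100", "2\ts2\t0\t200"), map)
  g <- read_genotypes(ped, format = "plink")
  expect_equal(unname(g$dosages[, 1]), c(1, 0, 2))  # dosage of minor allele A
  expect_true(is.na(g$dosages[2, 2]))
  expect_identical(g$chromosomes, c("1", "2"))
})

test_that("impute_and_center fills with column means and centers exactly", {
  g <- genotype_matrix(matrix(c(0, 1, 2), 3, 1), "s1")
  X <- impute_and_center(g)
  expect_equal(as.numeric(X), c(-1, 0, 1))
  expect_equal(unname(attr(X, "centers")), 1)

  g2 <- genotype_matrix(matrix(c(0, NA, 2), 3, 1), "s1")
  X2 <- impute_and_center(g2)
  expect_equal(as.numeric(X2), c(-1, 0, 1))
  expect_equal(unname(attr(X2, "centers")), 1)

  set.seed(42)
  M <- matrix(rbinom(600, 2, 0.3), 20, 30)
  M[sample(600, 40)] <- NA
  M[, 1] <- c(rep(NA, 19), 1)  # heavily missing but not all-missing
  X3 <- impute_and_center(genotype_matrix(M, paste0("s", 1:30)))
  expect_lt(max(abs(colSums(X3))), 1e-10)

  # idempotent on complete, already-centered input
  X4 <- impute_and_center(unclass(X3)[, , drop = FALSE])
  expect_equal(unname(unclass(X4)), unname(unclass(X3)), tolerance = 1e-12,
               ignore_attr = TRUE)

  g_bad <- genotype_matrix(matrix(NA_real_, 3, 1), "sZ")
  expect_error(impute_and_center(g_bad), "all dosages missing.*sZ")
})

test_that("phenotype IO round-trips and drops incomplete rows", {
  ph <- phenotype_table(matrix(c(1.5, 2.5, 3.5, 4, 5, 6), 3, 2),
                        trait_names = c("bf", "adg"),
                        individual_ids = c("a", "b", "c"))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(ph, tmp)
  ph2 <- read_phenotypes(tmp)
  expect_equal(ph2$values, ph$values)
  expect_identical(ph2$trait_names, c("bf", "adg"))

  expect_warning(
    ph3 <- phenotype_table(matrix(c(1, NA, 3, 4, 5, 6), 3, 2),
                           individual_ids = c("a", "b", "c")),
    "dropping 1 individual")
  expect_identical(ph3$individual_ids, c("a", "c"))
})

test_that("class maps resolve, collapse duplicates, and allow overlap", {
  g <- tiny_genotypes(m = 4)
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("snp_id,class_label", "s1,A", "s2,A", "s3,B", "s4,B", "s2,A"), tmp)
  al <- read_class_map(tmp, g)
  expect_identical(al$classes, c("A", "B"))
  expect_equal(lengths(al$members), c(A = 2L, B = 2L))

  writeLines(c("snp_id,class_label", "s1,A", "s1,B", "s2,B", "s3,A", "s4,B"), tmp)
  al2 <- read_class_map(tmp, g)
  expect_true(1L %in% al2$members$A && 1L %in% al2$members$B)

  writeLines(c("snp_id,class_label", "s1,A", "zz,B", "s2,B", "s3,B", "s4,A"), tmp)
  expect_error(read_class_map(tmp, g), "absent from the genotype map: zz")

  # member-set sizes equal distinct (snp, class) pair counts; write round trip
  al3 <- class_allocation(list(A = c(1, 3), B = c(1, 2, 4)), 4)
  out <- withr::local_tempfile(fileext = ".csv")
  write_class_map(al3, g, out)
  al4 <- read_class_map(out, g)
  expect_identical(al4$members, al3$members)
})
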