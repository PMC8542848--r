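test_that("inclusion labels enumerate all trait combinations deterministically", {
  expect_identical(unname(enumerate_inclusion_labels(1)),
                   matrix(c(0L, 1L), 2, 1))
  expect_identical(unname(enumerate_inclusion_labels(2)),
                   matrix(c(0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L), 4, 2))
  lab3 <- enumerate_inclusion_labels(3)
  expect_equal(nrow(lab3), 8L)
  expect_equal(nrow(unique(lab3)), 8L)  # every binary vector exactly once
  expect_equal(unname(lab3[1, ]), c(0L, 0L, 0L))
  expect_equal(unname(lab3[8, ]), c(1L, 1L, 1L))
})

test_that("default residual prior targets half the phenotypic variance", {
  rp <- default_residual_prior(2.0)
  expect_equal(rp$df_e, 4)
  expect_equal(rp$scale_e[1, 1], 0.5)  # E[s2] = df*S/(df-2) = 1.0
  expect_equal(rp$df_e * rp$scale_e[1, 1] / (rp$df_e - 2), 1.0)

  # t = 2: analytic prior mean S/(df-t-1) equals half the covariance
  rp2 <- default_residual_prior(diag(2))
  expect_equal(rp2$scale_e / (rp2$df_e - 3), diag(2) / 2)
  # Monte-Carlo check of the inverse-Wishart mean convention at a df where
  # the draw variance is finite (df = 4 with t = 2 has infinite variance)
  set.seed(1)
  draws <- rinvwishart(2e4, 6 * diag(2), df = 7)
  emp <- Reduce(`+`, draws) / length(draws)
  expect_equal(emp, 6 * diag(2) / (7 - 3), tolerance = 0.05)

  expect_error(default_residual_prior(matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("default marker prior scales with genotype variance and inclusion", {
  X1 <- matrix(c(-1, 0, 1), 3, 1)  # column variance 1
  ps <- default_marker_prior(matrix(1), X1, 1L, "RR-BLUP")
  expect_equal(ps$df_beta * ps$scale_beta[1, 1] / (ps$df_beta - 2), 0.5)

  # doubling all column variances halves the derived scale
  set.seed(2)
  X <- matrix(rnorm(200), 20, 10)
  s1 <- default_marker_prior(matrix(1), X, 1:10, "RR-BLUP")$scale_beta[1, 1]
  s2 <- default_marker_prior(matrix(1), X * sqrt(2), 1:10, "RR-BLUP")$scale_beta[1, 1]
  expect_equal(s2, s1 / 2)

  # inclusion probability 1/2 doubles the per-marker scale
  sC <- default_marker_prior(matrix(1), X, 1:10, "BayesCPi",
                             pi_init = c(0.5, 0.5))$scale_beta[1, 1]
  expect_equal(sC, 2 * s1)

  expect_error(default_marker_prior(matrix(1), matrix(1, 5, 2), 1:2, "RR-BLUP"),
               "zero genotypic variance")
})

test_that("LASSO default matches the double-exponential variance to the target", {
  set.seed(3)
  X <- matrix(rnorm(100), 20, 5)
  ps <- default_marker_prior(matrix(1), X, 1:5, "BayesianLASSO")
  rr <- default_marker_prior(matrix(1), X, 1:5, "RR-BLUP")
  # marginal DE variance (2/lambda^2) * scale equals the RR-BLUP per-marker target
  expect_equal(2 / ps$laplace_rate^2 * ps$laplace_scale[1, 1],
               rr$df_beta * rr$scale_beta[1, 1] / (rr$df_beta - 2))
})

test_that("constructor reductions map degenerate Pi to the nested priors", {
  red <- mcbayes:::normalize_prior(
    prior_spec("BayesCPi", pi_treatment = "fixed", pi_init = c(0, 1)), 1)
  expect_identical(red$kind, "RR-BLUP")
  red2 <- mcbayes:::normalize_prior(
    prior_spec("BayesB", pi_treatment = "fixed", pi_init = c(0, 0, 0, 1)), 2)
  expect_identical(red2$kind, "BayesA")
  # estimated Pi is not reduced
  keep <- mcbayes:::normalize_prior(
    prior_spec("BayesCPi", pi_init = c(0, 1)), 1)
  expect_identical(keep$kind, "BayesCPi")
  # uniform initialization gives 1/2^t per label
  unif <- mcbayes:::normalize_prior(prior_spec("BayesB"), 2)
  expect_equal(unif$pi_init, rep(1 / 4, 4))
  expect_equal(sum(unif$pi_init), 1)
  # prior means must exist
  expect_error(mcbayes:::normalize_prior(prior_spec("RR-BLUP", df_beta = 3), 2),
               "must exceed")
})

test_that("distribution helpers reproduce their analytic means", {
  set.seed(4)
  x <- rscaled_inv_chisq(1e5, df = 4, scale = 0.5)
  expect_equal(mean(x), 4 * 0.5 / 2, tolerance = 0.03)
  y <- rinvwishart(1e5, matrix(2), df = 4)
  expect_equal(mean(y), 2 / 2, tolerance = 0.03)  # t=1: S/(df-2)
})
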