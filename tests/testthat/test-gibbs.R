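test_that("constant phenotypes give zero effects and mu at the constant", {
  g <- tiny_genotypes(n = 40, m = 8, seed = 5)
  y <- rep(3.7, 40)
  spec <- model_spec(prior_spec("RR-BLUP", scale_beta = matrix(0.05)),
                     residual_prior = residual_prior(matrix(0.5)))
  fit <- run_mcmc(g, matrix(y, 40, 1), one_class(8), spec,
                  chain_config(1500, 500, seed = 9))
  expect_lt(max(abs(fit$alpha)), 0.05)
  expect_equal(unname(fit$mu), 3.7, tolerance = 0.05)
})

test_that("Gibbs matches the conjugate closed form on a 1-marker model", {
  set.seed(31)
  n <- 50
  x <- rbinom(n, 2, 0.4)
  y <- 0.8 * x + rnorm(n, 0, 1)
  xc <- x - mean(x); yc <- y - mean(y)
  s2a <- 0.3; s2e <- 1.0
  g <- genotype_matrix(matrix(x, n, 1), "s1")
  spec <- model_spec(
    prior_spec("RR-BLUP", df_beta = 4, scale_beta = matrix(s2a * (4 - 2) / 4)),
    residual_prior = residual_prior(matrix(s2e * (4 - 2) / 4)))
  fit <- run_mcmc(g, matrix(yc, n, 1), one_class(1), spec,
                  chain_config(2200, 200, thin = 1, seed = 12,
                               update_mu = FALSE, update_variances = FALSE,
                               update_residual = FALSE, save_effects = TRUE))
  a <- fit$samples$alpha[, 1]
  prec <- sum(xc^2) + s2e / s2a
  a_hat <- sum(xc * yc) / prec
  v_post <- s2e / prec
  # with fixed variances the draws are iid from the closed-form posterior
  expect_lt(abs(mean(a) - a_hat), 3 * sd(a) / sqrt(length(a)))
  expect_equal(var(a), v_post, tolerance = 5 * sqrt(2 / length(a)))
})

test_that("inclusion-label conditionals match grid integration (t = 2)", {
  set.seed(17)
  n <- 30
  x <- as.numeric(scale(rbinom(n, 2, 0.3), scale = FALSE))
  E <- matrix(rnorm(2 * n, 0, 0.8), n, 2)
  E[, 1] <- E[, 1] + 0.35 * x      # trait-1 signal only
  R <- matrix(c(1, 0.3, 0.3, 0.8), 2)
  G <- matrix(c(0.2, 0.05, 0.05, 0.15), 2)
  piv <- c(0.4, 0.2, 0.2, 0.2)
  got <- inclusion_label_probs(x, E, R, G, piv)

  # oracle: direct numerical integration of the marginal likelihood per label
  Rinv <- solve(R)
  r <- as.numeric(crossprod(E, x)); xtx <- sum(x^2)
  lik_kernel <- function(a) exp(-0.5 * xtx * drop(t(a) %*% Rinv %*% a) +
                                  drop(t(a) %*% Rinv %*% r))
  grid <- seq(-2, 2, length.out = 601)
  h <- diff(grid)[1]
  m00 <- 1
  m10 <- sum(vapply(grid, function(b) lik_kernel(c(b, 0)) *
                      stats::dnorm(b, 0, sqrt(G[1, 1])), numeric(1))) * h
  m01 <- sum(vapply(grid, function(b) lik_kernel(c(0, b)) *
                      stats::dnorm(b, 0, sqrt(G[2, 2])), numeric(1))) * h
  gg <- as.matrix(expand.grid(grid, grid))
  dens <- exp(-0.5 * rowSums((gg %*% solve(G)) * gg)) / (2 * pi * sqrt(det(G)))
  lik <- exp(-0.5 * xtx * rowSums((gg %*% Rinv) * gg) + drop(gg %*% Rinv %*% r))
  m11 <- sum(lik * dens) * h * h
  want <- piv * c(m00, m01, m10, m11)  # label order: (0,0),(0,1),(1,0),(1,1)
  want <- want / sum(want)
  expect_equal(got, want, tolerance = 1e-3)
})

test_that("a monomorphic (zero) genotype column leaves label probabilities at Pi", {
  E <- matrix(rnorm(20), 10, 2)
  pi <- c(0.1, 0.2, 0.3, 0.4)
  got <- inclusion_label_probs(rep(0, 10), E, diag(2), 0.2 * diag(2), pi)
  expect_equal(got, pi, tolerance = 1e-12)
})

test_that("identical seeds give bit-identical fits and clean bookkeeping", {
  d <- toy_dataset()
  spec <- model_spec("BayesCPi")
  f1 <- run_mcmc(d$g, d$ph, d$alloc, spec, chain_config(600, 200, seed = 21))
  f2 <- run_mcmc(d$g, d$ph, d$alloc, spec, chain_config(600, 200, seed = 21))
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$samples$Vg, f2$samples$Vg)
  # residual bookkeeping: y - mu - M alpha equals stored residuals
  expect_lt(f1$resid_drift, 1e-8)
  # alpha = delta * beta elementwise at all times
  expect_equal(f1$final$alpha, f1$final$delta * f1$final$beta, tolerance = 1e-14)
})

test_that("fixed Pi stays fixed and estimated Pi responds to the data", {
  d <- toy_dataset(n = 100, m = 30, seed = 5)
  pi0 <- c(0.3, 0.7)
  fitF <- run_mcmc(d$g, d$ph, one_class(30),
                   model_spec(prior_spec("BayesCPi", pi_treatment = "fixed",
                                         pi_init = pi0)),
                   chain_config(400, 100, seed = 2))
  expect_equal(as.numeric(fitF$class_pi$all), pi0, tolerance = 1e-12)
  fitE <- run_mcmc(d$g, d$ph, one_class(30), model_spec("BayesCPi"),
                   chain_config(800, 300, seed = 2))
  piE <- as.numeric(fitE$class_pi$all)
  expect_equal(sum(piE), 1, tolerance = 1e-12)
  expect_true(all(piE > 0))
})

test_that("Bayesian LASSO matches quadrature on a 1-marker model and shrinks with lambda", {
  set.seed(41)
  n <- 40
  x <- rbinom(n, 2, 0.5); xc <- x - mean(x)
  y <- 0.5 * xc + rnorm(n, 0, 1)
  yc <- y - mean(y)
  s2e <- 1.0; lam <- 2.0
  g <- genotype_matrix(matrix(x, n, 1), "s1")
  spec <- model_spec(
    prior_spec("BayesianLASSO", laplace_rate = lam, laplace_scale = matrix(1)),
    residual_prior = residual_prior(matrix(s2e * (4 - 2) / 4)))
  fit <- run_mcmc(g, matrix(yc, n, 1), one_class(1), spec,
                  chain_config(9000, 1000, thin = 1, seed = 8,
                               update_mu = FALSE, update_residual = FALSE,
                               save_effects = TRUE))
  post <- function(a) exp(-0.5 * sum((yc - xc * a)^2) / s2e - lam * abs(a))
  num <- stats::integrate(function(a) vapply(a, function(v) v * post(v), numeric(1)),
                          -2, 2, subdivisions = 500)$value
  den <- stats::integrate(function(a) vapply(a, post, numeric(1)),
                          -2, 2, subdivisions = 500)$value
  expect_equal(mean(fit$samples$alpha[, 1]), num / den, tolerance = 1e-2)

  # posterior mean |alpha| decreases as the rate lambda grows
  fit_big <- run_mcmc(g, matrix(yc, n, 1), one_class(1),
                      model_spec(prior_spec("BayesianLASSO", laplace_rate = 50,
                                            laplace_scale = matrix(1)),
                                 residual_prior = residual_prior(matrix(0.5))),
                      chain_config(3000, 500, seed = 8, update_mu = FALSE,
                                   update_residual = FALSE, save_effects = TRUE))
  expect_lt(mean(abs(fit_big$samples$alpha[, 1])),
            mean(abs(fit$samples$alpha[, 1])))
})

test_that("the GIG sampler reproduces quadrature moments across regimes", {
  dens <- function(x, p, chi, psi) x^(p - 1) * exp(-0.5 * (chi / x + psi * x))
  for (par in list(c(0, 1, 4), c(-0.5, 3, 1), c(1.5, 0.5, 2), c(0.5, 2, 3))) {
    z <- stats::integrate(dens, 0, Inf, p = par[1], chi = par[2], psi = par[3])$value
    m1 <- stats::integrate(function(x) x * dens(x, par[1], par[2], par[3]),
                           0, Inf)$value / z
    set.seed(77)
    draws <- vapply(1:30000, function(i) mcbayes:::.rgig_cpp(par[1], par[2], par[3]),
                    numeric(1))
    expect_equal(mean(draws), m1, tolerance = 4 * sd(draws) / sqrt(3e4) / m1 + 0.01,
                 label = sprintf("GIG mean p=%g chi=%g psi=%g", par[1], par[2], par[3]))
  }
})

test_that("predict_ebv applies training centers and matches the matrix product", {
  d <- toy_dataset(n = 60, m = 20, seed = 12)
  fit <- run_mcmc(d$g, d$ph, d$alloc, model_spec("RR-BLUP"),
                  chain_config(400, 100, seed = 4))
  pred <- predict_ebv(fit, d$g)
  expect_equal(pred, fit$ebv, tolerance = 1e-12, ignore_attr = TRUE)
  # locus-by-locus accumulation agrees with the matrix product
  Xc <- sweep(d$g$dosages, 2, fit$centers)
  manual <- rowSums(sapply(seq_len(20), function(j) Xc[, j] * fit$alpha[j, 1]))
  expect_equal(unname(pred[, 1]), unname(manual), tolerance = 1e-10)

  # zero-effect summary predicts zero
  fit0 <- fit; fit0$alpha[] <- 0
  expect_true(all(predict_ebv(fit0, d$g) == 0))
  # hand case: single marker effect 1.0 on dosages (0,1,2)
  fit1 <- fit
  fit1$alpha <- matrix(c(1, rep(0, 19)), 20, 1)
  dos <- d$g$dosages; dos[, 1] <- rep(c(0, 1, 2), 20)
  fit1$centers[1] <- 1
  expect_equal(unname(predict_ebv(fit1, dos)[1:3, 1]), c(-1, 0, 1))

  expect_error(predict_ebv(fit, d$g$dosages[, 1:5]), "5 markers")
})

test_that("overlapping classes contribute one effect term per membership", {
  d <- toy_dataset(n = 50, m = 10, seed = 3)
  over <- class_allocation(list(A = 1:6, B = 4:10), 10)
  fit <- run_mcmc(d$g, d$ph, over, model_spec("RR-BLUP"),
                  chain_config(300, 100, seed = 6))
  expect_equal(nrow(fit$alpha_entries), 13L)  # 6 + 7 entries
  # aggregated marker effect = sum of its entry effects
  j <- 5L  # member of both classes
  rows <- which(fit$entry_table$marker == fit$snp_ids[j])
  expect_length(rows, 2L)
  expect_equal(sum(fit$alpha_entries[rows, 1]), fit$alpha[j, 1], tolerance = 1e-12)
  expect_lt(fit$resid_drift, 1e-8)
})
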