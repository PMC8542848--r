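#' Enumerate trait-inclusion labels
#'
#' In multi-trait variable selection each locus may affect any combination of
#' traits. The combinations are represented by binary vectors
#' `delta = (delta_1, ..., delta_t)`; this returns all `2^t` of them in a
#' fixed deterministic order: binary counting with the last trait as the least
#' significant bit, so the first label is all-zeros (no trait affected) and the
#' last all-ones (all traits affected).
#'
#' @param t number of traits (>= 1).
#' @return A `2^t x t` binary integer matrix, one label per row.
#' @examples
#' enumerate_inclusion_labels(2)
#' @export
enumerate_inclusion_labels <- function(t) {
  if (!is_count(t) || t < 1L) stopf("t must be a positive integer")
  t <- as.integer(t)
  k <- 0:(2L^t - 1L)
  lab <- matrix(0L, length(k), t)
  for (j in seq_len(t)) lab[, j] <- as.integer((k %/% 2L^(t - j)) %% 2L)
  colnames(lab) <- paste0("trait", seq_len(t))
  lab
}

prior_kinds <- c("RR-BLUP", "BayesA", "BayesB", "BayesCPi", "BayesianLASSO")

match_prior_kind <- function(kind) {
  k <- tolower(gsub("[^a-z]", "", tolower(kind)))
  map <- c(rrblup = "RR-BLUP", rr = "RR-BLUP", blup = "RR-BLUP",
           bayesa = "BayesA", bayesb = "BayesB",
           bayesc = "BayesCPi", bayescpi = "BayesCPi",
           bayesianlasso = "BayesianLASSO", lasso = "BayesianLASSO",
           bl = "BayesianLASSO")
  if (!k %in% names(map)) stopf("unknown prior kind '%s'", kind)
  unname(map[[k]])
}

#' Bayesian Alphabet prior specification for one SNP class
#'
#' Describes the marker-effect prior of a class: the prior family, the
#' inverse-Wishart (multi-trait) or scaled-inverse-chi-square (single-trait)
#' hyperparameters of the effect (co)variance, the treatment of the
#' inclusion-probability vector Pi, and, for the Bayesian LASSO, the Laplace
#' rate and scale. Fields left `NULL` are filled with data-driven defaults by
#' [default_marker_prior()] when the model is fitted.
#'
#' Constructor reductions (applied when the trait count is known): BayesB with
#' Pi fixed at the all-ones label is BayesA, and BayesCPi with Pi fixed at the
#' all-ones label is RR-BLUP; such specifications are reduced so the
#' equivalent models produce identical Markov chains.
#'
#' @param kind one of `"RR-BLUP"`, `"BayesA"`, `"BayesB"`, `"BayesCPi"`,
#'   `"BayesianLASSO"` (case-insensitive aliases accepted).
#' @param df_beta prior degrees of freedom for the effect (co)variance
#'   (default 4).
#' @param scale_beta prior scale (scalar for one trait, `t x t` matrix
#'   otherwise), or `NULL` to derive from the phenotypic variance at fit time.
#' @param pi_treatment `"estimate"` (Pi sampled under its uniform prior) or
#'   `"fixed"`.
#' @param pi_init probability vector over the `2^t` inclusion labels in the
#'   order of [enumerate_inclusion_labels()]; `NULL` means uniform for
#'   BayesB/BayesCPi and a point mass on the all-ones label otherwise.
#' @param laplace_rate double-exponential rate `lambda > 0` (LASSO only).
#' @param laplace_scale Laplace scale matrix (LASSO, multi-trait), `NULL` to
#'   derive at fit time.
#' @return An object of class `PriorSpec`.
#' @export
prior_spec <- function(kind, df_beta = 4, scale_beta = NULL,
                       pi_treatment = c("estimate", "fixed"), pi_init = NULL,
                       laplace_rate = NULL, laplace_scale = NULL) {
  kind <- match_prior_kind(kind)
  pi_treatment <- match.arg(pi_treatment)
  if (!is.null(pi_init)) {
    pi_init <- as.numeric(pi_init)
    if (any(pi_init < 0) || abs(sum(pi_init) - 1) > 1e-9)
      stopf("pi_init must be a probability vector summing to 1")
    if (bitwAnd(length(pi_init), length(pi_init) - 1L) != 0L)
      stopf("pi_init length must be a power of two (one entry per inclusion label)")
  }
  if (!is.null(laplace_rate) && laplace_rate <= 0) stopf("laplace_rate must be > 0")
  structure(list(kind = kind, df_beta = df_beta, scale_beta = scale_beta,
                 pi_treatment = pi_treatment, pi_init = pi_init,
                 laplace_rate = laplace_rate, laplace_scale = laplace_scale),
            class = "PriorSpec")
}

#' @export
print.PriorSpec <- function(x, ...) {
  cat(sprintf("PriorSpec: %s (df_beta = %s, pi %s)\n", x$kind,
              format(x$df_beta), x$pi_treatment))
  invisible(x)
}

# Apply the constructor reductions and fill Pi defaults once t is known.
normalize_prior <- function(ps, t) {
  stopifnot(inherits(ps, "PriorSpec"))
  z <- 2L^t
  if (ps$kind %in% c("BayesB", "BayesCPi")) {
    if (is.null(ps$pi_init)) ps$pi_init <- rep(1 / z, z)
    if (length(ps$pi_init) != z)
      stopf("pi_init has %d entries; expected 2^%d = %d", length(ps$pi_init), t, z)
    all_ones <- abs(ps$pi_init[z] - 1) < 1e-12
    if (ps$pi_treatment == "fixed" && all_ones) {
      ps$kind <- if (ps$kind == "BayesB") "BayesA" else "RR-BLUP"
    }
  }
  if (ps$kind %in% c("RR-BLUP", "BayesA", "BayesianLASSO")) {
    ps$pi_init <- c(rep(0, z - 1L), 1)
    ps$pi_treatment <- "fixed"
  }
  if (is.null(ps$df_beta)) ps$df_beta <- 4
  if (ps$df_beta <= t + 1)
    stopf("df_beta = %s must exceed t + 1 = %d for the prior mean to exist",
          format(ps$df_beta), t + 1L)
  ps
}

#' Residual (co)variance prior
#'
#' Inverse-Wishart prior for the residual covariance of `t > 1` traits, or the
#' scaled inverse-chi-square prior for a single trait.
#'
#' @param scale_e prior scale (scalar for one trait, `t x t` matrix otherwise).
#' @param df_e prior degrees of freedom (default 4).
#' @return An object of class `ResidualPrior`.
#' @export
residual_prior <- function(scale_e, df_e = 4) {
  scale_e <- as.matrix(scale_e)
  t <- nrow(scale_e)
  if (df_e <= t + 1) stopf("df_e = %s must exceed t + 1 = %d", format(df_e), t + 1L)
  if (!is_pd(scale_e)) stopf("residual prior scale must be symmetric positive definite")
  structure(list(df_e = df_e, scale_e = scale_e), class = "ResidualPrior")
}

#' Default residual prior from the phenotypic (co)variance
#'
#' Chooses the scale so the prior mean of the residual covariance equals half
#' of the phenotypic (co)variance, with degrees of freedom 4 (raised to
#' `t + 2` when four would not exceed `t + 1`). Mean conventions: inverse
#' Wishart `E[R] = S / (df - t - 1)` for `t > 1`; scaled inverse chi-square
#' `E[sigma^2] = df * S / (df - 2)` for `t = 1`.
#'
#' @param phenotypic_cov phenotypic variance (scalar) or `t x t` covariance
#'   matrix.
#' @param df_e degrees of freedom (default 4).
#' @return A [residual_prior()].
#' @examples
#' default_residual_prior(2.0)  # prior mean of the residual variance is 1.0
#' @export
default_residual_prior <- function(phenotypic_cov, df_e = 4) {
  P <- as_cov_matrix(phenotypic_cov, t = if (is.null(dim(phenotypic_cov)))
    length(phenotypic_cov) else nrow(phenotypic_cov), "phenotypic covariance")
  t <- nrow(P)
  if (df_e <= t + 1) df_e <- t + 2
  target <- P / 2
  S <- if (t == 1L) target * (df_e - 2) / df_e else target * (df_e - t - 1)
  residual_prior(S, df_e)
}

#' Default marker-effect prior for one SNP class
#'
#' Derives the effect-(co)variance scale so the prior mean of the genetic
#' (co)variance contributed by the class equals half of the phenotypic
#' (co)variance apportioned by the class's share of markers. With `v_f` the
#' sample variance of centered genotype column `f`, the per-marker effect
#' (co)variance target is
#' `target = (phenotypic_cov / 2) * (|class| / m_total) / (sum(v_f) * pbar)`,
#' where `pbar` is the expected per-trait inclusion fraction under `pi_init`
#' (1 for RR-BLUP/BayesA/LASSO). The scale then follows the same mean
#' conventions as [default_residual_prior()]. For the Bayesian LASSO the
#' Laplace rate/scale are fixed so the marginal prior (co)variance of an
#' effect equals the same per-marker target (`2 / lambda^2` times the scale).
#'
#' @param phenotypic_cov phenotypic variance (scalar) or `t x t` matrix.
#' @param centered_genotypes centered covariate matrix from
#'   [impute_and_center()] (training individuals).
#' @param class_members integer indices of the class's markers.
#' @param kind prior family (see [prior_spec()]).
#' @param pi_init inclusion-label probabilities (default uniform for
#'   BayesB/BayesCPi).
#' @param df_beta degrees of freedom (default 4).
#' @param m_total total marker count used for the share apportionment
#'   (default `ncol(centered_genotypes)`).
#' @return A fully specified [prior_spec()].
#' @export
default_marker_prior <- function(phenotypic_cov, centered_genotypes,
                                 class_members, kind, pi_init = NULL,
                                 df_beta = 4, m_total = ncol(centered_genotypes)) {
  kind <- match_prior_kind(kind)
  P <- as_cov_matrix(phenotypic_cov, t = if (is.null(dim(phenotypic_cov)))
    length(phenotypic_cov) else nrow(phenotypic_cov), "phenotypic covariance")
  t <- nrow(P)
  class_members <- as.integer(class_members)
  if (length(class_members) == 0L) stopf("class is empty")
  v <- apply(centered_genotypes[, class_members, drop = FALSE], 2L, var)
  sumv <- sum(v)
  if (sumv <= 0) stopf("class has zero genotypic variance (all markers monomorphic)")
  z <- 2L^t
  if (is.null(pi_init)) {
    pi_init <- if (kind %in% c("BayesB", "BayesCPi")) rep(1 / z, z) else c(rep(0, z - 1L), 1)
  }
  labels <- enumerate_inclusion_labels(t)
  p_trait <- as.numeric(crossprod(labels, pi_init))
  pbar <- if (kind %in% c("BayesB", "BayesCPi")) mean(p_trait) else 1
  if (pbar <= 0) stopf("pi_init implies zero expected inclusion; cannot scale the prior")
  share <- length(class_members) / m_total
  target <- (P / 2) * share / (sumv * pbar)
  if (df_beta <= t + 1) df_beta <- t + 2
  if (kind == "BayesianLASSO") {
    return(prior_spec(kind, df_beta = df_beta,
                      laplace_rate = sqrt(2), laplace_scale = target))
  }
  S <- if (t == 1L) target * (df_beta - 2) / df_beta else target * (df_beta - t - 1)
  prior_spec(kind, df_beta = df_beta, scale_beta = S, pi_init = pi_init)
}

#' Multi-class model specification
#'
#' Binds one marker-effect prior to each SNP class, plus the residual prior.
#' Prior kinds may differ across classes (e.g. BayesA for one class and
#' BayesCPi for another).
#'
#' @param class_priors a single prior kind (recycled over all classes), a
#'   character vector of kinds, or a (optionally named) list of
#'   [prior_spec()] objects. Names, when present, must match the class labels
#'   of the allocation at fit time; unnamed entries are matched positionally.
#' @param trait_count number of traits `t` (default 1).
#' @param residual_prior a [residual_prior()], or `NULL` to derive the default
#'   from the phenotypic covariance at fit time.
#' @return An object of class `ModelSpec`.
#' @examples
#' model_spec("BayesCPi", trait_count = 2)
#' model_spec(list(coding = prior_spec("BayesA"), rest = prior_spec("RR-BLUP")))
#' @export
model_spec <- function(class_priors, trait_count = 1, residual_prior = NULL) {
  if (is.character(class_priors)) {
    class_priors <- lapply(class_priors, prior_spec)
  } else if (inherits(class_priors, "PriorSpec")) {
    class_priors <- list(class_priors)
  }
  if (!is.list(class_priors) || !all(vapply(class_priors, inherits, logical(1), "PriorSpec")))
    stopf("class_priors must be prior kinds or PriorSpec objects")
  if (!is.null(residual_prior) && !inherits(residual_prior, "ResidualPrior"))
    stopf("residual_prior must be a residual_prior() object")
  structure(list(trait_count = as.integer(trait_count),
                 class_priors = class_priors,
                 residual_prior = residual_prior),
            class = "ModelSpec")
}

#' @export
print.ModelSpec <- function(x, ...) {
  kinds <- vapply(x$class_priors, function(p) p$kind, character(1))
  nm <- names(x$class_priors)
  lab <- if (is.null(nm)) kinds else paste0(nm, ":", kinds)
  cat(sprintf("ModelSpec: %d trait(s); class priors [%s]\n",
              x$trait_count, paste(lab, collapse = ", ")))
  invisible(x)
}
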