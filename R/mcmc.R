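#' MCMC chain configuration
#'
#' @param chain_length total Gibbs iterations per chain (default 100000, the
#'   standard full-length analysis profile).
#' @param burn_in iterations discarded from the start (default 50000); must be
#'   smaller than `chain_length`.
#' @param thin keep every `thin`-th post-burn-in state in the stored samples
#'   (posterior means always use every post-burn-in state; default 10).
#' @param seed integer master seed; chains are reproducible (bit-identical)
#'   under the same seed. `NULL` leaves the RNG state untouched.
#' @param n_chains number of independent chains (seeds derived
#'   deterministically from `seed`); more than one enables the Gelman-Rubin
#'   diagnostic via [gelman_rubin()].
#' @param update_mu,update_variances,update_residual expert toggles that fix
#'   the overall mean, the marker-effect (co)variances, or the residual
#'   (co)variance at their initial values instead of sampling them; used for
#'   validation against closed-form posteriors.
#' @param save_effects also store thinned samples of every marker effect
#'   (memory grows with `m`; default FALSE).
#' @param verbose print a progress line every `verbose` iterations (0 = quiet).
#' @return An object of class `ChainConfig`.
#' @export
chain_config <- function(chain_length = 100000, burn_in = 50000, thin = 10,
                         seed = NULL, n_chains = 1, update_mu = TRUE,
                         update_variances = TRUE, update_residual = TRUE,
                         save_effects = FALSE, verbose = 0) {
  if (!is_count(chain_length) || chain_length < 2) stopf("chain_length must be >= 2")
  if (!is_count(burn_in) || burn_in >= chain_length)
    stopf("burn_in must be a non-negative integer smaller than chain_length")
  if (!is_count(thin) || thin < 1) stopf("thin must be a positive integer")
  if (!is_count(n_chains) || n_chains < 1) stopf("n_chains must be >= 1")
  structure(list(chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 n_chains = as.integer(n_chains),
                 update_mu = isTRUE(update_mu),
                 update_variances = isTRUE(update_variances),
                 update_residual = isTRUE(update_residual),
                 save_effects = isTRUE(save_effects),
                 verbose = as.integer(verbose)),
            class = "ChainConfig")
}

kernel_code <- c("RR-BLUP" = 0L, "BayesA" = 1L, "BayesB" = 2L,
                 "BayesCPi" = 3L, "BayesianLASSO" = 4L)

# Resolve inputs, apply constructor reductions, and fill default
# hyperparameters; returns everything the C++ engine needs.
compile_model <- function(X, Y, alloc, spec) {
  t <- ncol(Y)
  g <- length(alloc$classes)
  priors <- spec$class_priors
  nm <- names(priors)
  if (!is.null(nm) && any(nm != "")) {
    if (!setequal(nm, alloc$classes))
      stopf("class_priors names do not match allocation classes: [%s] vs [%s]",
            paste(nm, collapse = ","), paste(alloc$classes, collapse = ","))
    priors <- priors[alloc$classes]
  } else if (length(priors) == 1L) {
    priors <- rep(priors, g)
  } else if (length(priors) != g) {
    stopf("%d class priors supplied for %d classes", length(priors), g)
  }
  P <- if (t == 1L) matrix(var(as.numeric(Y)), 1, 1) else cov(Y)
  class_params <- vector("list", g)
  for (ci in seq_len(g)) {
    ps <- normalize_prior(priors[[ci]], t)
    members <- alloc$members[[alloc$classes[ci]]]
    needs_scale <- (ps$kind != "BayesianLASSO" && is.null(ps$scale_beta)) ||
      (ps$kind == "BayesianLASSO" && is.null(ps$laplace_scale))
    if (needs_scale) {
      dflt <- default_marker_prior(P, X, members, ps$kind, pi_init = ps$pi_init,
                                   df_beta = ps$df_beta, m_total = ncol(X))
      if (ps$kind == "BayesianLASSO") {
        ps$laplace_scale <- dflt$laplace_scale
        ps$laplace_rate <- ps$laplace_rate %||% dflt$laplace_rate
      } else {
        ps$scale_beta <- dflt$scale_beta
      }
    }
    if (ps$kind == "BayesianLASSO") {
      if (is.null(ps$laplace_rate) || ps$laplace_rate <= 0)
        stopf("Bayesian LASSO class '%s' needs laplace_rate > 0", alloc$classes[ci])
      if (is.null(ps$laplace_scale)) ps$laplace_scale <- diag(t)
      ps$scale_beta <- ps$scale_beta %||% diag(t)
    }
    Sb <- as.matrix(ps$scale_beta)
    if (!all(dim(Sb) == c(t, t))) stopf("scale_beta for class '%s' must be %dx%d",
                                        alloc$classes[ci], t, t)
    class_params[[ci]] <- list(kernel = kernel_code[[ps$kind]],
                               S_beta = Sb, nu_beta = ps$df_beta,
                               pi = ps$pi_init,
                               pi_fixed = ps$pi_treatment == "fixed",
                               lambda = ps$laplace_rate %||% 0,
                               laplace_scale = as.matrix(ps$laplace_scale %||% diag(t)))
    priors[[ci]] <- ps
  }
  rp <- spec$residual_prior %||% default_residual_prior(P)
  if (nrow(rp$scale_e) != t) stopf("residual prior dimension != trait count")
  entry_marker <- unlist(alloc$members[alloc$classes], use.names = FALSE)
  entry_class <- rep(seq_len(g), vapply(alloc$members[alloc$classes], length, integer(1)))
  list(class_params = class_params, priors = priors, residual = rp,
       entry_marker = as.integer(entry_marker), entry_class = as.integer(entry_class),
       labels = enumerate_inclusion_labels(t), t = t, g = g)
}

#' Fit a multi-class Bayesian Alphabet model by Gibbs sampling
#'
#' Fits the whole-genome regression
#' `y_i = mu + sum_l sum_{f in C_l} m_{if} alpha_f + e_i`
#' in which every SNP class `C_l` carries its own Bayesian Alphabet prior.
#' One full sweep per iteration updates, in order: the overall mean; each
#' class's loci (inclusion indicator and effect drawn jointly, with the effect
#' integrated out of the indicator's full conditional for BayesB/BayesCPi);
#' the marker-effect (co)variances and class inclusion probabilities; and the
#' residual (co)variance.
#'
#' @param genotypes a [genotype_matrix()], or a pre-centered covariate matrix
#'   from [impute_and_center()].
#' @param phenotypes a [phenotype_table()], or a numeric vector/matrix aligned
#'   with the genotype rows.
#' @param alloc a [class_allocation()]; a marker allocated to several classes
#'   contributes one effect term per class.
#' @param spec a [model_spec()].
#' @param cfg a [chain_config()].
#' @return An object of class `PosteriorSummary` with posterior means of all
#'   parameters, estimated breeding values for the training individuals,
#'   thinned samples of the variance components (pooled and per chain), and
#'   the genotype centering means needed by [predict_ebv()].
#' @seealso [predict_ebv()], [genomic_heritability()], [genetic_correlation()]
#' @examples
#' set.seed(1)
#' g <- simulate_genotypes(sim_config(n_individuals = 80, n_snps = 60,
#'                                    heritabilities = 0.5, seed = 1))
#' alloc <- allocate_by_chromosome(g)
#' sim <- simulate_traits(sim_config(n_individuals = 80, n_snps = 60,
#'                                   n_qtl_enriched = 5, n_qtl_genomewide = 2,
#'                                   enriched_class = "chr1",
#'                                   heritabilities = 0.5, seed = 1), g, alloc)
#' fit <- run_mcmc(g, sim$phenotypes, alloc, model_spec("RR-BLUP"),
#'                 chain_config(500, 200, seed = 1))
#' genomic_heritability(fit)
#' @export
run_mcmc <- function(genotypes, phenotypes, alloc, spec, cfg = chain_config()) {
  stopifnot(inherits(alloc, "ClassAllocation"), inherits(spec, "ModelSpec"),
            inherits(cfg, "ChainConfig"))
  if (inherits(genotypes, "GenotypeMatrix")) {
    X <- impute_and_center(genotypes)
    gids <- genotypes$individual_ids
  } else {
    X <- genotypes
    gids <- rownames(X)
  }
  centers <- attr(X, "centers") %||% rep(0, ncol(X))
  snp_ids <- colnames(X) %||% paste0("snp", seq_len(ncol(X)))
  if (inherits(phenotypes, "PhenotypeTable")) {
    Y <- phenotypes$values
    pids <- phenotypes$individual_ids
    if (!is.null(gids)) {
      keep <- intersect(gids, pids)
      if (length(keep) < 2L) stopf("fewer than 2 individuals shared between genotypes and phenotypes")
      if (length(keep) < length(gids) || length(keep) < length(pids))
        warnf("using %d individual(s) present in both genotypes and phenotypes", length(keep))
      X <- X[match(keep, gids), , drop = FALSE]
      Y <- Y[match(keep, pids), , drop = FALSE]
    }
  } else {
    Y <- as.matrix(phenotypes)
    if (nrow(Y) != nrow(X)) stopf("phenotype rows (%d) != genotype rows (%d)", nrow(Y), nrow(X))
  }
  storage.mode(Y) <- "double"
  if (ncol(Y) != spec$trait_count)
    stopf("model specifies %d trait(s) but phenotypes have %d", spec$trait_count, ncol(Y))
  if (alloc$m != ncol(X)) stopf("allocation is over %d markers; genotypes have %d", alloc$m, ncol(X))
  cm <- compile_model(X, Y, alloc, spec)

  run_one <- function(chain) {
    if (!is.null(cfg$seed)) {
      s <- if (cfg$n_chains == 1L) cfg$seed else derive_seed(cfg$seed, chain)
      set.seed(s)
    }
    .mc_gibbs_cpp(X, Y, cm$entry_marker - 1L, cm$entry_class - 1L,
                  cm$class_params, cm$residual$scale_e, cm$residual$df_e,
                  cm$labels, cfg$chain_length, cfg$burn_in, cfg$thin,
                  cfg$update_mu, cfg$update_residual, cfg$update_variances,
                  cfg$save_effects, cfg$verbose)
  }
  raws <- lapply(seq_len(cfg$n_chains), run_one)

  t <- cm$t; g <- cm$g
  trait_names <- colnames(Y) %||% paste0("trait", seq_len(t))
  avg <- function(get) Reduce(`+`, lapply(raws, get)) / length(raws)
  mean_alpha <- avg(function(r) r$mean_alpha)
  # aggregate entry-level effects to one substitution effect per marker
  alpha_marker <- matrix(0, ncol(X), t, dimnames = list(snp_ids, trait_names))
  for (k in seq_along(cm$entry_marker)) {
    j <- cm$entry_marker[k]
    alpha_marker[j, ] <- alpha_marker[j, ] + mean_alpha[k, ]
  }
  pooled <- list()
  for (nmx in names(raws[[1]]$samples)) {
    pooled[[nmx]] <- do.call(rbind, lapply(raws, function(r) r$samples[[nmx]]))
  }
  if (!cfg$save_effects) pooled$alpha <- NULL
  colnames(pooled$h2) <- trait_names
  colnames(pooled$mu) <- trait_names
  avg_list <- function(get) setNames(lapply(seq_len(g), function(ci) {
    Reduce(`+`, lapply(raws, function(r) get(r)[[ci]])) / length(raws)
  }), alloc$classes)
  class_cov <- avg_list(function(r) r$mean_class_cov)
  class_pi <- avg_list(function(r) r$mean_pi)
  kinds <- vapply(cm$priors, function(p) p$kind, character(1))
  ebv <- X %*% alpha_marker
  rownames(ebv) <- rownames(Y)
  structure(list(
    alpha = alpha_marker,
    alpha_entries = mean_alpha,
    entry_table = data.frame(class = alloc$classes[cm$entry_class],
                             marker = snp_ids[cm$entry_marker],
                             stringsAsFactors = FALSE),
    mu = setNames(as.numeric(avg(function(r) r$mean_mu)), trait_names),
    residual_cov = avg(function(r) r$mean_R),
    class_cov = class_cov,
    class_pi = class_pi,
    locus_cov = avg(function(r) r$mean_locus_cov),
    ebv = ebv,
    samples = pooled,
    chains = lapply(raws, function(r) r$samples),
    final = raws[[1]]$final,
    kinds = setNames(kinds, alloc$classes),
    trait_names = trait_names,
    snp_ids = snp_ids,
    centers = centers,
    n = nrow(Y), m = ncol(X),
    config = cfg,
    resid_drift = max(vapply(raws, function(r) r$resid_drift, numeric(1))),
    n_jitter = sum(vapply(raws, function(r) r$n_jitter, numeric(1)))),
    class = "PosteriorSummary")
}

#' @export
print.PosteriorSummary <- function(x, ...) {
  cat(sprintf("PosteriorSummary: %d individuals, %d markers, %d trait(s), %d chain(s)\n",
              x$n, x$m, length(x$trait_names), length(x$chains)))
  cat(sprintf("  class priors: %s\n",
              paste(names(x$kinds), x$kinds, sep = "=", collapse = ", ")))
  h2 <- colMeans(x$samples$h2)
  cat(sprintf("  posterior mean genomic h2: %s\n",
              paste(sprintf("%s=%.3f", x$trait_names, h2), collapse = ", ")))
  invisible(x)
}

#' Estimated breeding values for (new) individuals
#'
#' Multiplies centered genotype dosages by the posterior-mean allele
#' substitution effects. Validation individuals are centered with the
#' training-time column means stored in the fit, so predictions are on the
#' training scale.
#'
#' @param summary a `PosteriorSummary` from [run_mcmc()].
#' @param genotypes a [genotype_matrix()] or dosage matrix whose columns match
#'   the training markers (checked by SNP id when available).
#' @return An `n x t` matrix of estimated breeding values.
#' @export
predict_ebv <- function(summary, genotypes) {
  stopifnot(inherits(summary, "PosteriorSummary"))
  dos <- if (inherits(genotypes, "GenotypeMatrix")) genotypes$dosages else as.matrix(genotypes)
  if (ncol(dos) != summary$m)
    stopf("genotypes have %d markers; model was trained on %d", ncol(dos), summary$m)
  if (!is.null(colnames(dos)) && !identical(colnames(dos), summary$snp_ids))
    stopf("marker columns do not match the training SNP ids/order")
  if (anyNA(dos)) {
    for (j in which(colSums(is.na(dos)) > 0L)) dos[is.na(dos[, j]), j] <- summary$centers[j]
  }
  Xc <- sweep(dos, 2L, summary$centers)
  Xc %*% summary$alpha
}

#' Posterior genomic heritability
#'
#' Per-trait posterior mean of `Vg / (Vg + Ve)`, where `Vg` is the variance of
#' the genomic values `M alpha` across individuals at each stored MCMC state
#' and `Ve` the corresponding residual variance.
#'
#' @param summary a `PosteriorSummary` from [run_mcmc()].
#' @return Named numeric vector, one entry per trait.
#' @export
genomic_heritability <- function(summary) {
  stopifnot(inherits(summary, "PosteriorSummary"))
  colMeans(summary$samples$h2)
}

#' Posterior genetic correlation between two traits
#'
#' Posterior mean of the correlation implied by the per-state genomic
#' covariance matrix.
#'
#' @param summary a `PosteriorSummary` from a multi-trait [run_mcmc()] fit.
#' @param traits indices (or names) of the two traits (default first two).
#' @return Posterior-mean genetic correlation.
#' @export
genetic_correlation <- function(summary, traits = c(1, 2)) {
  stopifnot(inherits(summary, "PosteriorSummary"))
  t <- length(summary$trait_names)
  if (t < 2) stopf("genetic correlation needs at least two traits")
  ix <- if (is.character(traits)) match(traits, summary$trait_names) else as.integer(traits)
  Vg <- summary$samples$Vg
  i <- ix[1]; j <- ix[2]
  num <- Vg[, (j - 1) * t + i]
  den <- sqrt(Vg[, (i - 1) * t + i] * Vg[, (j - 1) * t + j])
  mean(num / den)
}

#' Full-conditional probabilities of the trait-inclusion labels at one locus
#'
#' Computes, for a single locus, the posterior probability of each of the
#' `2^t` inclusion labels with the effect vector integrated out analytically —
#' the same kernel the Gibbs sampler uses for BayesB/BayesCPi loci. Exposed
#' for validation against direct numerical integration.
#'
#' @param x centered genotype column (length n).
#' @param resid `n x t` residual matrix with this locus's contribution removed
#'   (i.e. adjusted for all other effects).
#' @param R residual covariance (`t x t`, or scalar for one trait).
#' @param G effect covariance for the locus (`t x t`, or scalar).
#' @param pi prior probability of each label, in [enumerate_inclusion_labels()]
#'   order.
#' @return Numeric vector of label probabilities summing to 1.
#' @export
inclusion_label_probs <- function(x, resid, R, G, pi) {
  resid <- as.matrix(resid)
  t <- ncol(resid)
  R <- as_cov_matrix(R, t, "residual covariance")
  G <- as_cov_matrix(G, t, "effect covariance")
  labels <- enumerate_inclusion_labels(t)
  if (length(pi) != nrow(labels)) stopf("pi must have 2^t entries")
  r <- as.numeric(crossprod(resid, x))
  as.numeric(.label_probs_cpp(sum(x^2), r, solve(R), solve(G), pi, labels))
}

#' Random draws from the inverse-Wishart distribution
#'
#' Parameterized so that `E[W] = S / (df - t - 1)` for a `t x t` scale `S`.
#'
#' @param n number of draws.
#' @param S scale matrix.
#' @param df degrees of freedom (`> t + 1` for the mean to exist).
#' @return A list of `n` matrices (a numeric vector when `t = 1`).
#' @export
rinvwishart <- function(n, S, df) {
  S <- as.matrix(S)
  draws <- lapply(seq_len(n), function(i) .riwish_cpp(S, df))
  if (nrow(S) == 1L) vapply(draws, function(d) d[1, 1], numeric(1)) else draws
}

#' Random draws from the scaled inverse-chi-square distribution
#'
#' Parameterized as `df * scale / chisq(df)`, so `E[x] = df * scale / (df - 2)`.
#'
#' @param n number of draws.
#' @param df degrees of freedom.
#' @param scale scale parameter.
#' @return Numeric vector of draws.
#' @export
rscaled_inv_chisq <- function(n, df, scale) {
  vapply(seq_len(n), function(i) .rscinvchisq_cpp(df, scale), numeric(1))
}
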