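#' Cross-validation plans with an 8:2 train/validation split
#'
#' Each replicate is an independent uniform random split of the individuals;
#' the training-set size is `round(ratio * n)` (round-half-even).
#'
#' @param n number of individuals (>= 5).
#' @param n_replicates number of replicate splits.
#' @param ratio training fraction in (0, 1) (default 0.8).
#' @param seed integer seed making the whole set of plans reproducible.
#' @return A list of `CVPlan` objects with fields `replicate`, `train`,
#'   `validation`, `ratio`, `seed`.
#' @export
make_cv_plan <- function(n, n_replicates, ratio = 0.8, seed = NULL) {
  if (!is_count(n) || n < 5) stopf("n must be an integer >= 5")
  if (!is_count(n_replicates) || n_replicates < 1) stopf("n_replicates must be >= 1")
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) stopf("ratio must be in (0, 1)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_train <- as.integer(round(ratio * n))
  if (n_train < 1L || n_train >= n) stopf("ratio %g leaves no training or validation individuals", ratio)
  lapply(seq_len(n_replicates), function(rep) {
    train <- sort(sample.int(n, n_train))
    structure(list(replicate = rep, train = train,
                   validation = setdiff(seq_len(n), train),
                   ratio = ratio, seed = seed),
              class = "CVPlan")
  })
}

#' Prediction accuracy as the Pearson correlation
#'
#' Correlation between estimated breeding values and the phenotypic records of
#' the validation individuals.
#'
#' @param ebv numeric vector of estimated breeding values.
#' @param phenotypes numeric vector of the same length (>= 3).
#' @return Pearson correlation coefficient.
#' @export
prediction_accuracy <- function(ebv, phenotypes) {
  ebv <- as.numeric(ebv); phenotypes <- as.numeric(phenotypes)
  if (length(ebv) != length(phenotypes)) stopf("ebv and phenotypes differ in length")
  if (length(ebv) < 3L) stopf("need at least 3 observations")
  if (sd(ebv) == 0 || sd(phenotypes) == 0)
    stopf("accuracy undefined: constant input vector")
  cor(ebv, phenotypes)
}

#' Ensemble prediction across methods
#'
#' Elementwise arithmetic mean of the estimated breeding values from several
#' fitted methods.
#'
#' @param ebv_by_method list (or matrix with one column per method) of
#'   equal-length EBV vectors.
#' @return Numeric vector of ensemble EBVs.
#' @export
ensemble_ebv <- function(ebv_by_method) {
  if (is.matrix(ebv_by_method)) ebv_by_method <- asplit(ebv_by_method, 2L)
  lens <- vapply(ebv_by_method, length, integer(1))
  if (length(unique(lens)) != 1L) stopf("EBV vectors differ in length")
  Reduce(`+`, lapply(ebv_by_method, as.numeric)) / length(ebv_by_method)
}

#' Paired t-test on replicate-paired accuracies
#'
#' Two-sided paired t-test on the per-replicate accuracy differences between
#' two methods; significance declared at `alpha` (default 0.1). Zero variance
#' of the differences yields p = 1 (logged, never significant).
#'
#' @param acc_a,acc_b equal-length accuracy vectors, paired by replicate.
#' @param alpha significance level (default 0.1).
#' @return A list with `t` (statistic), `p` (two-sided p-value), `significant`
#'   (logical), `mean_diff`.
#' @export
paired_t_test <- function(acc_a, acc_b, alpha = 0.1) {
  acc_a <- as.numeric(acc_a); acc_b <- as.numeric(acc_b)
  if (length(acc_a) != length(acc_b)) stopf("accuracy vectors differ in length")
  if (length(acc_a) < 2L) stopf("need at least 2 paired replicates")
  d <- acc_a - acc_b
  if (sd(d) == 0) {
    message("paired_t_test: zero variance of differences; p set to 1")
    return(list(t = NA_real_, p = 1, significant = FALSE, mean_diff = mean(d)))
  }
  ht <- stats::t.test(acc_a, acc_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       significant = ht$p.value < alpha, mean_diff = mean(d))
}

#' Gelman-Rubin potential scale reduction factor
#'
#' For `k >= 2` chains of `s` samples of a scalar parameter, computes
#' `PSRF = sqrt(1 + B / (s * W))`, where `B / s` is the variance of the chain
#' means and `W` the mean within-chain variance — the between/within variance
#' ratio without the finite-sample deflation term, so identical chains give
#' exactly 1 and values near 1 indicate convergence.
#'
#' @param chains `k x s` numeric matrix (one chain per row), or a list of
#'   equal-length numeric vectors.
#' @return The potential scale reduction factor.
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) {
    lens <- vapply(chains, length, integer(1))
    if (length(unique(lens)) != 1L) stopf("chains differ in length")
    chains <- do.call(rbind, lapply(chains, as.numeric))
  }
  chains <- as.matrix(chains)
  k <- nrow(chains); s <- ncol(chains)
  if (k < 2L) stopf("Gelman-Rubin diagnostic needs at least 2 chains")
  if (s < 10L) stopf("need at least 10 samples per chain")
  W <- mean(apply(chains, 1L, var))
  B_over_s <- var(rowMeans(chains))
  if (W == 0) return(if (B_over_s == 0) 1 else Inf)
  sqrt(1 + B_over_s / W)
}

#' Cross-validated comparison of class schemes and prior methods
#'
#' Runs the full replicate x method x class-scheme grid: for each
#' cross-validation plan, fits every (scheme, method) combination on the
#' training individuals, predicts the validation individuals, and records the
#' Pearson accuracy per trait. When `ensemble = TRUE` and several methods are
#' run, the ensemble (mean EBV across methods) is scored per scheme as well.
#' A replicate whose accuracy is undefined (constant EBVs or phenotypes) is
#' logged and recorded as `NA`, and excluded from downstream means.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes a [phenotype_table()] (individuals aligned by id).
#' @param schemes named list of [class_allocation()] objects (e.g.
#'   `list(conventional = one_class, multiclass = by_annotation)`).
#' @param methods character vector of prior kinds applied uniformly over each
#'   scheme's classes.
#' @param plans list of plans from [make_cv_plan()].
#' @param cfg a [chain_config()]; its seed is re-derived per fit so every cell
#'   of the grid is reproducible.
#' @param ensemble score the across-method ensemble too (default TRUE when
#'   more than one method).
#' @param truth optional `TruthRecord` from [simulate_traits()]; when given,
#'   an extra column `accuracy_vs_truth` reports the correlation between the
#'   EBVs and the simulated true breeding values (labelled separately because
#'   it is not available for real data).
#' @return A data frame (the accuracy table) with columns `replicate`,
#'   `scheme`, `method`, `trait`, `accuracy` (and `accuracy_vs_truth` when
#'   `truth` is supplied).
#' @export
cross_validate <- function(genotypes, phenotypes, schemes, methods, plans,
                           cfg = chain_config(), ensemble = length(methods) > 1,
                           truth = NULL) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"), inherits(phenotypes, "PhenotypeTable"))
  safe_accuracy <- function(a, b, what) {
    tryCatch(prediction_accuracy(a, b), error = function(e) {
      message("cross_validate: ", what, ": ", conditionMessage(e),
              " (recorded as NA)")
      NA_real_
    })
  }
  if (is.null(names(schemes))) stopf("schemes must be a named list of allocations")
  ids <- intersect(genotypes$individual_ids, phenotypes$individual_ids)
  dos <- genotypes$dosages[match(ids, genotypes$individual_ids), , drop = FALSE]
  Y <- phenotypes$values[match(ids, phenotypes$individual_ids), , drop = FALSE]
  BV <- if (!is.null(truth))
    truth$breeding_values[match(ids, genotypes$individual_ids), , drop = FALSE]
  t <- ncol(Y)
  trait_names <- colnames(Y)
  out <- list(); oi <- 1L
  for (plan in plans) {
    tr <- plan$train; va <- plan$validation
    gtr <- genotype_matrix(dos[tr, , drop = FALSE], genotypes$snp_ids,
                           genotypes$chromosomes, genotypes$positions,
                           ids[tr])
    for (sc in names(schemes)) {
      ebvs <- list()
      for (me in methods) {
        fit_cfg <- cfg
        fit_cfg$seed <- if (is.null(cfg$seed)) NULL else
          derive_seed(cfg$seed, plan$replicate * 1000L +
                        match(sc, names(schemes)) * 100L + match(me, methods))
        fit <- run_mcmc(gtr, phenotype_table(Y[tr, , drop = FALSE],
                                             individual_ids = ids[tr]),
                        schemes[[sc]], model_spec(me, trait_count = t), fit_cfg)
        pred <- predict_ebv(fit, dos[va, , drop = FALSE])
        ebvs[[me]] <- pred
        for (s in seq_len(t)) {
          row <- data.frame(replicate = plan$replicate, scheme = sc,
                            method = me, trait = trait_names[s],
                            accuracy = safe_accuracy(pred[, s], Y[va, s],
                              paste(sc, me, trait_names[s])),
                            stringsAsFactors = FALSE)
          if (!is.null(truth))
            row$accuracy_vs_truth <- safe_accuracy(pred[, s], BV[va, s], "truth")
          out[[oi]] <- row
          oi <- oi + 1L
        }
      }
      if (isTRUE(ensemble) && length(methods) > 1L) {
        for (s in seq_len(t)) {
          ens <- ensemble_ebv(lapply(ebvs, function(e) e[, s]))
          row <- data.frame(replicate = plan$replicate, scheme = sc,
                            method = "Ensemble", trait = trait_names[s],
                            accuracy = safe_accuracy(ens, Y[va, s],
                              paste(sc, "ensemble", trait_names[s])),
                            stringsAsFactors = FALSE)
          if (!is.null(truth))
            row$accuracy_vs_truth <- safe_accuracy(ens, BV[va, s], "truth")
          out[[oi]] <- row
          oi <- oi + 1L
        }
      }
    }
  }
  do.call(rbind, out)
}
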