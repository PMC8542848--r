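#' Run the end-to-end analysis pipeline from a configuration file
#'
#' Executes, in order: optional simulation of genotypes/classes/phenotypes;
#' class allocation (from a class-map file, annotation file, chromosomes, or
#' the simulated classes); model fitting for every requested method x
#' class-scheme combination; and cross-validated evaluation. A run manifest
#' (configuration snapshot, derived seeds, input checksums, package version,
#' timestamp) is written first so the run can be reproduced bit-identically.
#'
#' The configuration is a YAML file; see the package README for the schema.
#' Every stage derives its seed deterministically from the single master
#' `seed` key.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list.
#' @param output_dir output directory (created if needed); defaults to the
#'   config's `output_dir` entry.
#' @return Invisibly, a list with the accuracy table (if evaluation ran), the
#'   fits of the full-data models (if requested), and the manifest path.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stopf("config must be a YAML file path or a named list")
  out <- output_dir %||% cfg$output_dir %||% stopf("config needs an 'output_dir'")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)

  # fail fast on missing inputs before any computation
  for (key in c("genotypes", "phenotypes", "class_map", "annotation")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p)) stopf("config '%s' path does not exist: %s", key, p)
  }

  manifest <- list(
    config = cfg, seed = seed,
    derived_seeds = list(simulate = derive_seed(seed, 10L),
                         cv = derive_seed(seed, 20L), fit = derive_seed(seed, 30L)),
    inputs = lapply(Filter(Negate(is.null), cfg[c("genotypes", "phenotypes",
                                                  "class_map", "annotation")]),
                    function(p) unname(tools::md5sum(p))),
    version = as.character(packageVersion("mcbayes")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  truth <- NULL
  if (isTRUE(cfg$simulate$enabled) || (is.null(cfg$genotypes) && !is.null(cfg$simulate))) {
    sc <- do.call(sim_config, modifyList(
      list(seed = manifest$derived_seeds$simulate),
      cfg$simulate[setdiff(names(cfg$simulate), c("enabled"))]))
    g <- simulate_genotypes(sc)
    alloc_sim <- assign_annotation_classes(sc, g)
    sim <- simulate_traits(sc, g, alloc_sim)
    ph <- sim$phenotypes
    truth <- sim$truth
    write_genotypes(g, file.path(out, "genotypes.csv"))
    write_phenotypes(ph, file.path(out, "phenotypes.csv"))
    write_class_map(alloc_sim, g, file.path(out, "class_map.csv"))
    utils::write.csv(data.frame(qtl_index = truth$qtl_idx, truth$effects),
                     file.path(out, "qtl_truth.csv"), row.names = FALSE)
  } else {
    g <- read_genotypes(cfg$genotypes, format = cfg$genotype_format %||% "csv",
                        map = cfg$genotype_map)
    ph <- read_phenotypes(cfg$phenotypes)
    alloc_sim <- NULL
  }

  schemes <- list(conventional = class_allocation(list(all = seq_len(ncol(g$dosages))),
                                                  ncol(g$dosages)))
  alloc_multi <- if (!is.null(cfg$class_map)) read_class_map(cfg$class_map, g)
    else if (!is.null(cfg$annotation)) allocate_by_annotation(cfg$annotation, g)
    else if (identical(cfg$allocation, "chromosome")) allocate_by_chromosome(g)
    else alloc_sim
  if (!is.null(alloc_multi)) schemes$multiclass <- alloc_multi

  methods <- cfg$methods %||% "RR-BLUP"
  t <- length(ph$trait_names)
  mcfg <- chain_config(chain_length = cfg$chain_length %||% 2000,
                       burn_in = cfg$burn_in %||% 1000,
                       thin = cfg$thin %||% 10,
                       seed = manifest$derived_seeds$fit,
                       n_chains = cfg$n_chains %||% 1)

  fits <- NULL
  if (isTRUE(cfg$fit_full %||% TRUE)) {
    fits <- list()
    for (sc in names(schemes)) {
      for (me in methods) {
        key <- paste(sc, me, sep = ".")
        fit_cfg <- mcfg
        fit_cfg$seed <- derive_seed(mcfg$seed, match(sc, names(schemes)) * 10L +
                                      match(me, methods))
        spec <- if (!is.null(cfg$class_priors) && sc != "conventional") {
          model_spec(lapply(cfg$class_priors, prior_spec), trait_count = t)
        } else model_spec(me, trait_count = t)
        fit <- run_mcmc(g, ph, schemes[[sc]], spec, fit_cfg)
        fits[[key]] <- fit
        utils::write.csv(data.frame(snp_id = fit$snp_ids, fit$alpha),
                         file.path(out, paste0("effects_", key, ".csv")),
                         row.names = FALSE)
        utils::write.csv(data.frame(id = rownames(fit$ebv) %||% seq_len(fit$n), fit$ebv),
                         file.path(out, paste0("ebv_", key, ".csv")), row.names = FALSE)
      }
    }
  }

  acc <- NULL
  if (isTRUE(cfg$evaluate$enabled %||% FALSE)) {
    plans <- make_cv_plan(length(intersect(g$individual_ids, ph$individual_ids)),
                          n_replicates = cfg$evaluate$n_replicates %||% 5,
                          ratio = cfg$evaluate$ratio %||% 0.8,
                          seed = manifest$derived_seeds$cv)
    acc <- cross_validate(g, ph, schemes, methods, plans, mcfg, truth = truth)
    utils::write.csv(acc, file.path(out, "accuracy.csv"), row.names = FALSE)
    report <- compare_schemes(acc, alpha = cfg$evaluate$alpha %||% 0.1)
    utils::write.csv(report, file.path(out, "comparison.csv"), row.names = FALSE)
  }
  invisible(list(accuracy = acc, fits = fits, manifest = manifest_path,
                 output_dir = out, truth = truth))
}

#' Summarize a cross-validation accuracy table into a scheme comparison
#'
#' Mean accuracy per (method, trait) for each class scheme plus the paired
#' t-test between the multi-class and conventional schemes across replicates.
#'
#' @param acc accuracy table from [cross_validate()].
#' @param alpha significance level for the paired t-test (default 0.1).
#' @return Data frame with one row per (method, trait): mean accuracies per
#'   scheme, mean difference, t statistic, p value, significance flag.
#' @export
compare_schemes <- function(acc, alpha = 0.1) {
  schemes <- unique(acc$scheme)
  if (length(schemes) != 2L) stopf("compare_schemes expects exactly 2 schemes, got %d", length(schemes))
  ref <- if ("conventional" %in% schemes) "conventional" else schemes[1]
  alt <- setdiff(schemes, ref)
  rows <- list(); i <- 1L
  for (me in unique(acc$method)) {
    for (tr in unique(acc$trait)) {
      a <- acc[acc$method == me & acc$trait == tr & acc$scheme == alt, ]
      b <- acc[acc$method == me & acc$trait == tr & acc$scheme == ref, ]
      a <- a[order(a$replicate), ]; b <- b[order(b$replicate), ]
      ok <- !is.na(a$accuracy) & !is.na(b$accuracy)
      tt <- paired_t_test(a$accuracy[ok], b$accuracy[ok], alpha = alpha)
      rows[[i]] <- data.frame(method = me, trait = tr,
                              mean_multiclass = mean(a$accuracy, na.rm = TRUE),
                              mean_conventional = mean(b$accuracy, na.rm = TRUE),
                              mean_diff = tt$mean_diff, t = tt$t, p = tt$p,
                              significant = tt$significant,
                              stringsAsFactors = FALSE)
      i <- i + 1L
    }
  }
  do.call(rbind, rows)
}
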