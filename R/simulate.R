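# Default annotation-class proportions: the composition of a commercial pig
# 60K panel after QC (protein coding 15084, non-coding RNA 1840, processed
# pseudogene 107, intergenic 24838, pseudogene 377 of 42246 SNPs).
default_class_proportions <- function() {
  counts <- c(protein_coding = 15084, ncRNA = 1840, processed_pseudogene = 107,
              intergenic = 24838, pseudogene = 377)
  counts / sum(counts)
}

#' Simulation configuration
#'
#' Defines the synthetic study conditions: LD-free binomial genotypes,
#' multinomial annotation classes with a realistic genome composition, QTL
#' enriched in one annotation class plus a handful spread genome-wide, and
#' pleiotropic QTL effects drawn from a multivariate normal with unit
#' variances and correlation 0.5, scaled to target heritabilities of 0.5 and
#' 0.9 for the two default traits.
#'
#' @param n_individuals number of individuals.
#' @param n_snps number of SNPs.
#' @param maf_range interval within (0, 0.5] for the per-SNP minor allele
#'   frequency (default c(0.05, 0.5)).
#' @param n_chromosomes chromosomes the SNPs are spread evenly over
#'   (default 18).
#' @param class_proportions named probability vector over annotation labels
#'   (default: the pig-panel composition above).
#' @param n_qtl_enriched QTL drawn from the enriched class (default 500).
#' @param enriched_class label of the QTL-enriched class
#'   (default "protein_coding").
#' @param n_qtl_genomewide additional QTL drawn from the whole genome,
#'   disjoint from the enriched set (default 20).
#' @param heritabilities per-trait narrow-sense heritability targets in (0, 1]
#'   (default c(0.5, 0.9)); the length sets the trait count.
#' @param qtl_effect_cov `t x t` covariance of the pleiotropic QTL effects
#'   (default unit diagonal with off-diagonals 0.5).
#' @param seed integer seed; each generator stage derives its own stream from
#'   it so the genotypes, classes, and traits are individually reproducible.
#' @return An object of class `SimulationConfig`.
#' @export
sim_config <- function(n_individuals, n_snps, maf_range = c(0.05, 0.5),
                       n_chromosomes = 18,
                       class_proportions = default_class_proportions(),
                       n_qtl_enriched = 500, enriched_class = "protein_coding",
                       n_qtl_genomewide = 20, heritabilities = c(0.5, 0.9),
                       qtl_effect_cov = NULL, seed = NULL) {
  if (!is_count(n_individuals) || n_individuals < 1) stopf("n_individuals must be >= 1")
  if (!is_count(n_snps) || n_snps < 1) stopf("n_snps must be >= 1")
  maf_range <- as.numeric(maf_range)
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stopf("maf_range must be an interval within (0, 0.5]")
  if (is.null(names(class_proportions)))
    stopf("class_proportions must be named by annotation label")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stopf("class_proportions must sum to 1 (got %.12f)", sum(class_proportions))
  heritabilities <- as.numeric(heritabilities)
  if (any(heritabilities <= 0 | heritabilities > 1))
    stopf("heritabilities must lie in (0, 1]")
  t <- length(heritabilities)
  if (is.null(qtl_effect_cov)) {
    qtl_effect_cov <- matrix(0.5, t, t); diag(qtl_effect_cov) <- 1
  }
  qtl_effect_cov <- as_cov_matrix(qtl_effect_cov, t, "qtl_effect_cov")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 n_chromosomes = as.integer(n_chromosomes),
                 class_proportions = class_proportions,
                 n_qtl_enriched = as.integer(n_qtl_enriched),
                 enriched_class = enriched_class,
                 n_qtl_genomewide = as.integer(n_qtl_genomewide),
                 heritabilities = heritabilities,
                 qtl_effect_cov = qtl_effect_cov,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate LD-free genotype dosages
#'
#' Per-SNP allele frequencies are drawn uniformly from `maf_range` and
#' dosages as independent Binomial(2, p) counts — linkage-free genotypes that
#' isolate the statistical behaviour of the priors from LD structure. SNPs
#' are spread evenly over the chromosomes with increasing positions.
#'
#' @param cfg a [sim_config()].
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (!is.null(cfg$seed)) set.seed(derive_seed(cfg$seed, 1L))
  n <- cfg$n_individuals; m <- cfg$n_snps
  p <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  dos <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  chrom <- rep(seq_len(cfg$n_chromosomes), length.out = m)
  chrom <- sort(chrom)
  pos <- integer(m)
  for (cc in unique(chrom)) pos[chrom == cc] <- seq_len(sum(chrom == cc)) * 10000L
  genotype_matrix(dos, snp_ids = sprintf("snp%05d", seq_len(m)),
                  chromosomes = chrom, positions = pos,
                  individual_ids = sprintf("ind%05d", seq_len(n)))
}

#' Assign annotation classes to simulated SNPs
#'
#' Each SNP receives one annotation label multinomially according to
#' `class_proportions`; the induced [class_allocation()] is returned with the
#' per-SNP annotation table attached as attribute `"annotation"` (so it can be
#' written with [write_class_map()]).
#'
#' @param cfg a [sim_config()].
#' @param g the simulated [genotype_matrix()].
#' @return A [class_allocation()].
#' @export
assign_annotation_classes <- function(cfg, g) {
  stopifnot(inherits(cfg, "SimulationConfig"), inherits(g, "GenotypeMatrix"))
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9)
    stopf("class_proportions must sum to 1")
  if (!is.null(cfg$seed)) set.seed(derive_seed(cfg$seed, 2L))
  m <- ncol(g$dosages)
  lab <- sample(names(cfg$class_proportions), m, replace = TRUE,
                prob = cfg$class_proportions)
  present <- names(cfg$class_proportions)[names(cfg$class_proportions) %in% lab]
  members <- split(seq_len(m), factor(lab, levels = present))
  alloc <- class_allocation(members, m)
  attr(alloc, "annotation") <- data.frame(snp_id = g$snp_ids, feature_type = lab,
                                          stringsAsFactors = FALSE)
  alloc
}

#' Simulate phenotypes with class-enriched QTL
#'
#' Draws `n_qtl_enriched` QTL uniformly without replacement from the enriched
#' class and `n_qtl_genomewide` further QTL from the rest of the genome (the
#' two sets are disjoint). Each QTL's `t`-vector effect is sampled from
#' MVN(0, `qtl_effect_cov`); true breeding values are the dosage-weighted
#' effect sums; per-trait residual variances are calibrated to the *realized*
#' genetic variance, `var(g) * (1 - h2) / h2`, so the target heritability
#' holds per replicate; residuals are independent across traits (trait
#' correlation is induced genetically).
#'
#' @param cfg a [sim_config()].
#' @param g the simulated [genotype_matrix()].
#' @param alloc a [class_allocation()] containing `enriched_class`.
#' @return A list with elements `phenotypes` (a [phenotype_table()]) and
#'   `truth` (class `TruthRecord`: `qtl_idx`, `qtl_enriched`, `qtl_genomewide`,
#'   `effects`, `breeding_values`, `residual_sd`, `heritabilities`).
#' @export
simulate_traits <- function(cfg, g, alloc) {
  stopifnot(inherits(cfg, "SimulationConfig"), inherits(g, "GenotypeMatrix"),
            inherits(alloc, "ClassAllocation"))
  if (!cfg$enriched_class %in% alloc$classes)
    stopf("enriched class '%s' not present in the allocation", cfg$enriched_class)
  enr <- alloc$members[[cfg$enriched_class]]
  if (length(enr) < cfg$n_qtl_enriched)
    stopf("enriched class has %d SNPs; %d QTL requested", length(enr), cfg$n_qtl_enriched)
  if (!is.null(cfg$seed)) set.seed(derive_seed(cfg$seed, 3L))
  m <- ncol(g$dosages)
  t <- length(cfg$heritabilities)
  qtl_enr <- sort(sample(enr, cfg$n_qtl_enriched))
  rest <- setdiff(seq_len(m), qtl_enr)
  if (length(rest) < cfg$n_qtl_genomewide)
    stopf("not enough remaining SNPs for %d genome-wide QTL", cfg$n_qtl_genomewide)
  qtl_gw <- sort(sample(rest, cfg$n_qtl_genomewide))
  qtl <- c(qtl_enr, qtl_gw)
  L <- chol(cfg$qtl_effect_cov)
  effects <- matrix(rnorm(length(qtl) * t), length(qtl), t) %*% L
  gv <- g$dosages[, qtl, drop = FALSE] %*% effects
  vg <- apply(gv, 2L, var)
  if (any(vg <= 0)) stopf("degenerate genetic variance; increase n or QTL count")
  res_sd <- sqrt(vg * (1 - cfg$heritabilities) / cfg$heritabilities)
  yv <- gv + matrix(rnorm(nrow(gv) * t), nrow(gv), t) %*% diag(res_sd, t)
  colnames(yv) <- paste0("trait", seq_len(t))
  ph <- phenotype_table(yv, individual_ids = g$individual_ids)
  truth <- structure(list(qtl_idx = qtl, qtl_enriched = qtl_enr,
                          qtl_genomewide = qtl_gw, effects = effects,
                          breeding_values = gv, residual_sd = res_sd,
                          heritabilities = cfg$heritabilities),
                     class = "TruthRecord")
  list(phenotypes = ph, truth = truth)
}
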