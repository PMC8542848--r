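# mcbayes — multi-class Bayesian Alphabet models for genomic prediction

`mcbayes` is an R package for single-trait and multiple-trait whole-genome
Bayesian regression in which markers are allocated — possibly overlappingly —
into SNP classes (genome annotations, chromosomes, a GWAS-derived focal set)
and **each class receives its own Bayesian Alphabet prior**: RR-BLUP, BayesA,
BayesB, BayesCPi, or the Bayesian LASSO, in any combination within one model.
It is aimed at quantitative geneticists who want to inject biological
information into genomic prediction without leaving the familiar Bayesian
Alphabet machinery.

The model for individual *i* with *t* traits is

```
y_i = mu + sum_{l=1..g} sum_{f in C_l} m_{if} * alpha_f^(l) + e_i
```

with dosage covariates `m_{if}` (coded 0/1/2, mean-centered), class-specific
priors on the substitution effects `alpha`, a flat prior on `mu`, and an
inverse-Wishart (scaled inverse chi-square for one trait) residual prior whose
mean is half the phenotypic (co)variance. Multi-trait BayesB/BayesCPi let
every locus affect any of the `2^t` trait combinations through inclusion
indicators `delta` with per-class probabilities `Pi` under a uniform prior.
Inference is single-site Gibbs sampling (compiled with RcppArmadillo), with
the indicator drawn jointly with the effect (effect integrated out
analytically). The package also ships the supporting machinery of a full
study: a QTL simulator with class-enriched architecture, 8:2 cross-validation
with Pearson accuracy, a five-method ensemble, paired *t*-tests at alpha =
0.1, and Gelman–Rubin convergence diagnostics.

## Worked example

Simulate a 300-individual, 1000-SNP dataset whose QTL are enriched in the
protein-coding class, then fit a multi-class BayesCPi model:

```r
library(mcbayes)

cfg <- sim_config(n_individuals = 300, n_snps = 1000, n_qtl_enriched = 50,
                  n_qtl_genomewide = 5, heritabilities = 0.5, seed = 42)
g     <- simulate_genotypes(cfg)
alloc <- assign_annotation_classes(cfg, g)
sim   <- simulate_traits(cfg, g, alloc)

fit <- run_mcmc(g, sim$phenotypes, alloc, model_spec("BayesCPi"),
                chain_config(2000, 1000, seed = 42))
fit
#> PosteriorSummary: 300 individuals, 1000 markers, 1 trait(s), 1 chain(s)
#>   class priors: protein_coding=BayesCPi, ncRNA=BayesCPi, processed_pseudogene=BayesCPi, intergenic=BayesCPi, pseudogene=BayesCPi
#>   posterior mean genomic h2: trait1=0.660

signif(sapply(fit$class_cov, function(G) G[1, 1]), 3)
#>       protein_coding                ncRNA processed_pseudogene
#>               1.0900               0.0677               0.1180
#>           intergenic           pseudogene
#>               0.0530               0.0816

prediction_accuracy(predict_ebv(fit, g)[, 1], sim$truth$breeding_values[, 1])
#> [1] 0.818
```

The per-class effect variances show the model discovering the enrichment: the
protein-coding class (which holds 50 of the 55 simulated QTL) is assigned a
~20x larger marker-effect variance than the intergenic background, and the
resulting EBVs correlate 0.82 with the simulated true breeding values. The
genomic heritability (0.66 here against a 0.5 target) carries the sampling
noise of a 300-individual estimate; at the package's reference size
(n = 1000, m = 3000) it is recovered to within a few hundredths — see below.

Cross-validated comparison of a multi-class scheme against the conventional
one-class model:

```r
schemes <- list(conventional = class_allocation(list(all = 1:1000), 1000),
                multiclass   = alloc)
plans <- make_cv_plan(300, n_replicates = 5, seed = 1)
acc <- cross_validate(g, sim$phenotypes, schemes,
                      c("RR-BLUP", "BayesCPi"), plans,
                      chain_config(800, 200, seed = 1))
compare_schemes(acc)   # means, paired-t p-values, significance at alpha = 0.1
```

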