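---
title: "Multi-class Bayesian Alphabet models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-class Bayesian Alphabet models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcbayes)
```

## The model

Whole-genome regression predicts breeding values by regressing phenotypes on
all genotyped markers simultaneously. Conventional Bayesian Alphabet methods
assume every marker effect comes from the same prior family, which ignores
biological structure: markers in protein-coding genes, in regulatory RNA, or
near a known GWAS signal plausibly follow different effect-size
distributions. `mcbayes` fits, for individual $i$ with $t$ traits,

$$
\mathbf{y}_i \;=\; \boldsymbol\mu \;+\;
\sum_{l=1}^{g}\;\sum_{f \in C_l} m_{if}\,\boldsymbol\alpha_{f}^{(l)}
\;+\; \mathbf{e}_i ,
$$

where markers are allocated to $g$ SNP classes $C_1,\dots,C_g$ and **each
class carries its own Bayesian Alphabet prior** on its allele substitution
effects $\boldsymbol\alpha$. The allocation may overlap: a marker in $k$
classes contributes $k$ additive effect terms, one under each class's prior
(its total substitution effect is their sum). The overall mean is the only
fixed effect and has a flat prior; the residuals are i.i.d. multivariate
normal with covariance $\mathbf{R}$.

Available class priors:

* **RR-BLUP** — common normal prior, class-level effect covariance
  $\mathbf{G}$;
* **BayesA** — locus-specific covariance $\mathbf{G}_f$ (marginally a
  scaled-$t$ prior);
* **BayesB** — BayesA plus trait-inclusion indicators;
* **BayesCPi** — common covariance plus trait-inclusion indicators and an
  estimated inclusion-probability vector $\Pi$;
* **Bayesian LASSO** — double-exponential (single trait) or multivariate
  Laplace (multi-trait) prior via a scale mixture of normals.

Different kinds can coexist in one model (e.g. BayesA on the protein-coding
class and BayesCPi on the rest), which is the package's reason to exist.

### Variable selection across traits

In multi-trait BayesB/BayesCPi each locus may affect any combination of
traits. The effect is written $\boldsymbol\alpha_f = \mathbf{D}_f
\boldsymbol\beta_f$ with $\mathbf{D}_f = \mathrm{diag}(\boldsymbol\delta_f)$
and $\boldsymbol\delta_f \in \{0,1\}^t$. The $2^t$ labels are enumerated in a
fixed order (`enumerate_inclusion_labels()`); each class has its own label
probability vector $\Pi$ with a uniform (Dirichlet all-ones) prior, updated
as $\Pi \mid \delta \sim \mathrm{Dirichlet}(1 + \text{label counts})$ unless
fixed.

### Priors and hyperparameter elicitation

* Residual: inverse Wishart ($t>1$) or scaled inverse chi-square ($t=1$) with
  degrees of freedom 4 and scale chosen so the **prior mean of the residual
  covariance is half the phenotypic covariance**. Mean conventions:
  $E[\mathbf{R}] = \mathbf{S}_e/(\nu_e - t - 1)$ and
  $E[\sigma^2] = \nu S/(\nu-2)$. With $t \ge 3$ a prior df of 4 leaves no
  finite mean, so the default df is raised to $t+2$.
* Marker effects: same conventions with $\nu_\beta = 4$; the scale is chosen
  so the prior mean of the **total genetic covariance equals half the
  phenotypic covariance**, apportioned to each class proportionally to its
  marker count and divided by the class's summed genotype variances and by
  the expected inclusion fraction under $\Pi$'s initial value. With one class
  and no selection this reproduces the conventional default exactly; a
  BayesCPi class with inclusion probability 1/2 gets twice the per-marker
  scale of an RR-BLUP class.
* Bayesian LASSO: the rate/scale are fixed so the marginal prior variance of
  an effect, $2/\lambda^2$ times the scale, equals the same per-marker
  target; there is no hyperprior on $\lambda$.

The df choice $\nu_\beta = 4$ is applied uniformly to all five families,
including the locus-specific BayesA/BayesB covariances.

## The Gibbs sampler

One iteration sweeps, in a fixed order chosen for reproducibility: the
overall mean (normal full conditional under the flat prior); every class in
declared order and its loci in index order; the variance components and
$\Pi$; and the residual covariance. At a BayesB/BayesCPi locus the indicator
$\boldsymbol\delta$ is drawn from its full conditional over the $2^t$ labels
**with $\boldsymbol\beta$ integrated out analytically** (required for
adequate mixing), then $\boldsymbol\beta$ from its multivariate-normal full
conditional given the label. Residuals are maintained incrementally by
rank-one updates and refreshed exactly every 500 sweeps; the final drift is
reported in the fit (`resid_drift`, typically $<10^{-12}$).

Conjugate bookkeeping for the covariance updates: the full effect vector is
instantiated at every locus whose label is not all-zeros, so a locus
contributes $\boldsymbol\beta\boldsymbol\beta'$ with one degree of freedom to
its (locus- or class-level) inverse-Wishart update; all-zero loci are
collapsed out and contribute nothing. This keeps the prior invariant
(a sampler run with no effective data reproduces the prior means of all
variance components) — the alternative of counting only the included *trait*
components would not.

For the Bayesian LASSO the scale-mixture representation
$\boldsymbol\alpha\mid v \sim N(0, v\,\Sigma)$, $v \sim
\mathrm{Exp}(\lambda^2/2)$ gives the double-exponential/multivariate Laplace
marginal; $v$'s full conditional is generalized inverse Gaussian
$\mathrm{GIG}(1 - t/2,\ \boldsymbol\alpha'\Sigma^{-1}\boldsymbol\alpha,\
\lambda^2)$, sampled with Devroye's rejection algorithm (inverse-Gaussian
shortcut at $t=1$). The GIG and inverse-Wishart samplers are validated
against quadrature in the test suite.

Numerical safeguards: covariance draws that fail the Cholesky factorization
get $10^{-8}$ diagonal jitter with up to five retries (counted and reported);
non-finite residuals abort with the iteration index; a monomorphic (zero
after centering) column leaves the label probabilities at $\Pi$ exactly.

### Reductions and determinism

BayesA **is** BayesB with $\Pi$ fixed at the all-ones label, and RR-BLUP
**is** BayesCPi with $\Pi$ fixed at all-ones. These reductions are applied
when the model is compiled, so equivalent specifications consume identical
random numbers and produce **bit-identical chains** under the same seed, as
does a one-class multi-class model versus the conventional model. All
randomness flows through R's RNG; with `n_chains > 1` each chain's seed is
derived deterministically from the master seed.

Chain defaults are 100,000 iterations with 50,000 burn-in (the full-length
analysis profile) and thinning 10 for stored samples; posterior means always
use every post-burn-in state. Reduced lengths are passed explicitly
everywhere in the examples and tests, with the problem sizes stated below.

## What the simulator emulates — and what it does not

`simulate_genotypes()` draws LD-free dosages, Binomial(2, $p_f$) with $p_f
\sim U(0.05, 0.5)$, spread evenly over 18 chromosomes;
`assign_annotation_classes()` labels SNPs multinomially with a realistic
genome composition (protein coding 0.357, non-coding RNA 0.044, processed
pseudogene 0.003, intergenic 0.588, pseudogene 0.009 — the composition of a
commercial pig panel after QC); `simulate_traits()` places 500 QTL in the
protein-coding class plus 20 genome-wide (disjoint sets, both drawn
uniformly without replacement), samples pleiotropic effects from
$N(\mathbf{0}, \mathbf{G}_0)$ with unit variances and correlation 0.5, and
calibrates per-trait residual variances to the **realized** genetic variance
so the target heritabilities (0.5 and 0.9 by default) hold per replicate;
residuals are independent across traits, so trait correlation is induced
genetically.

What passing tests on these data do **not** show about real data: there is
no linkage disequilibrium, no relatedness/pedigree structure, no selection,
and annotation labels are independent of allele frequency. Accuracy levels
on real panels depend on all of these. The simulation isolates the
statistical behaviour of the priors — in particular, whether concentrating
prior variance on a QTL-enriched class helps — which is exactly what the
reduced-scale comparison in the test suite measures.

## Estimator precision and problem sizes

The package's headline check recovers genomic heritability
($V_g/(V_g+V_e)$, with $V_g$ the variance of $\mathbf{M}\boldsymbol\alpha$
across individuals at each stored state) by single-trait RR-BLUP at
$n=1000$, $m=3000$, 5,000 iterations/2,500 burn-in. At these sizes the
heritability estimator itself has a dataset-to-dataset sampling SD of about
$\sqrt{2m}/n \approx 0.08$ — a property of GREML-type estimation, not of the
sampler (the posterior matches an independent GRM-ML fit on the same data to
two decimals). The acceptance computation therefore averages the posterior
estimate over replicate simulated datasets (8 in `scripts/acceptance.R`, 5 in
the test suite), bringing the SD to ~0.03; the genetic-correlation check
averages 2 replicates. The reduced-scale directional comparison uses 10
datasets of $n=600$, $m=2000$ with 100 + 5 QTL, 5 cross-validation splits
each and 800/200 chains — chain lengths chosen as the shortest at which the
EBV ranking is stable on this problem class.

## Other design choices

* **Centering.** Genotype columns are mean-centered before fitting (the
  covariates are coded 0/1/2; centering decouples $\mu$ from allele
  frequencies). No variance scaling is applied. Validation individuals are
  centered with the training means. Missing dosages are mean-imputed;
  phenotype rows with any missing trait are dropped at preparation.
* **Training-set size** in cross-validation is `round(0.8 n)`
  (round-half-even); the paired $t$-test between schemes is two-sided at
  $\alpha = 0.1$ with no multiplicity correction, and a zero-variance
  difference vector reports $p = 1$.
* **Accuracy** is the Pearson correlation between EBVs and validation
  *phenotypes* (accuracy against simulated true breeding values can be
  computed from the returned `TruthRecord` but is reported separately).
* **Gelman–Rubin.** The PSRF is computed as $\sqrt{1 + B/(sW)}$ ($B/s$ the
  variance of chain means, $W$ the mean within-chain variance), the variant
  without the $(s-1)/s$ deflation term, so identical chains give exactly 1.
* **Overlap policy.** A SNP carrying several annotation feature types joins
  every matching class rather than being assigned by priority; unannotated
  SNPs fall into the absorbing class `intergenic`.
* **Two QTL sets.** The 20 genome-wide QTL are drawn from the complement of
  the 500 enriched QTL; allowing coincidence would double-count effects.

## Known limitations

Only the overall mean is supported as a fixed effect; there is no
missing-phenotype machinery, no single-step extension to non-genotyped
individuals, no window-based association summaries, and no BayesR-style
multi-component mixtures. The simulator does not model LD, so prior
families that exploit LD structure are not differentiated by it.

## A small worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_individuals = 300, n_snps = 1000, n_qtl_enriched = 50,
                  n_qtl_genomewide = 5, heritabilities = 0.5, seed = 42)
g     <- simulate_genotypes(cfg)
alloc <- assign_annotation_classes(cfg, g)
sim   <- simulate_traits(cfg, g, alloc)

fit <- run_mcmc(g, sim$phenotypes, alloc, model_spec("BayesCPi"),
                chain_config(2000, 1000, seed = 42))
genomic_heritability(fit)
sapply(fit$class_cov, function(G) G[1, 1])  # per-class effect variances
```
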