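---
title: "Methods: genomic prediction with weighted kinship and machine learning"
author: "pigGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic prediction with weighted kinship and machine learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
choices that were genuinely open, and what its simulations do and do not
establish. No empirical claim is made here beyond what the test suite and
`scripts/acceptance.R` compute.

## The setting

A small purebred pig herd (about 515 genotyped sows) with three lowly
heritable reproduction traits — litter weight, total number born, number born
alive, heritabilities in the 0.15–0.21 range — and chip-scale genotypes. The
pipeline asks two questions: how does prediction accuracy respond to the
*number* of GWAS-ranked markers used, and does *weighting* trait-associated
loci inside the relationship matrix help.

## Synthetic data: what it emulates, and what it does not

No real genotypes ship with the package; `simulateGenotypes()` and
`simulatePhenotypes()` generate everything at run time.

* **Genotypes** come from a block-wise Gaussian-copula threshold model: each
  LD block carries a latent AR(1) Gaussian process (correlation
  `withinBlockCorr`, default 0.6) thresholded at the per-SNP
  allele-frequency quantile; two independent haplotypes per animal are
  summed into dosages. Every SNP is marginally in Hardy–Weinberg
  proportions (property-tested), adjacent SNPs within a block are
  positively correlated, and blocks are independent. This gives seedable,
  dependency-free LD control. It does **not** reproduce coalescent LD
  decay, demographic history, sex chromosomes or genotyping error; the
  block parameters are knobs, not estimates of any real population's LD.
* **Traits** are additive: a sparse set of QTL (default 100 of 10,000
  markers) receives N(0, 1) effects, rescaled so the sample variance of the
  breeding values equals the target h²; Gaussian noise supplies the
  remaining 1 − h²; categorical year/month/litter-size effects (three, twelve
  and eight levels, level effects N(0, 0.5²)) sit on top. Defaults follow
  the study conditions: 515 animals, h² = 0.19, 18 autosomes.
* **Chip masking** (`maskToChip()`) keeps a uniform random marker subset as
  a "chip" panel against the full matrix as sequencing truth, which is all
  the imputation-concordance metric needs. Imputation itself is out of
  scope.

Because effect sizes are drawn N(0, 1), a five-QTL architecture routinely
contains one locus explaining under half a percent of the phenotypic
variance — statistically invisible at n = 400 to any method. Recovery
experiments therefore score planted QTL per locus, with a sharper assertion
for loci above 2% variance explained.

## Phenotype correction

`y = Xb + e` by ordinary least squares (`stats::lm` behind the module
surface), with year and month categorical and litter size configurable per
trait. Records beyond 3 SD from the residual mean are removed **once** (the
threshold and an iterated variant are configurable, since published analyses
rarely state the rule); residuals are standardized with the n − 1 sample SD.
Downstream accuracies are correlations, so the SD convention is cosmetic but
documented. A single extreme point can inflate the SD enough to shield
itself at 3 SD — the filter makes no attempt to outwit that; use a tighter
rule or the iterated variant if the data call for it.

## SNP quality control

Stages run in fixed order: positionless/sex-chromosome markers, call rate
(< 0.95), MAF (< 0.01, computed among non-missing calls, PLINK-like), and a
1-df chi-square Hardy–Weinberg test (p < 1e-6) — the common chip-QC choices
at these sample sizes (an exact HWE test would be the alternative at small
counts). The ledger object enforces `final = initial − Σ removals` at
construction, and `applyQc()` is idempotent by test. Concordance between an
imputed and a truth matrix counts identical 0/1/2 dosages per locus over a
sample subset, bins loci at accuracy 0.3/0.6/0.9, and flags accuracy-1 loci
for retention.

## GWAS, PC covariates and density panels

Association is the marginal least-squares fit of `yc` on dosage plus
covariates, computed by projecting trait and dosages off the covariate space
once (algebraically the joint fit, validated against a normal-equation
oracle at 1e-8). Population structure enters through principal components of
the mean-imputed, unit-variance-standardized dosage matrix; components are
kept when their Tracy–Widom p-value is below 0.01 (30 components examined by
default).

Two numerical choices deserve note. The TW p-value uses the Chiani
shifted-gamma approximation of the TW(β=1) distribution function — closed
form and accurate to about 1e-3 where selection operates — instead of an
interpolated quantile table. The effective-marker moment estimator is
derived to be exact in expectation for a null Wishart spectrum,
`n̂ = (m+1)S₁²/(mS₂ − S₁²)`, and is computed *leaving the tested eigenvalue
out*, otherwise the tested value's own fluctuation partially normalizes
itself away and the test becomes conservative by about one standard
deviation. With these choices the leading-component test is calibrated on
null genotypes (about 1% fire at p < 0.01, about 10% at p < 0.1, verified by
simulation); deeper components in the remove-and-retest recursion remain
conservative, a known property of that recipe, so on structureless data the
procedure selects essentially nothing beyond the calibrated leading test.

Density panels rank SNPs by ascending p with genome-order tie-breaks; the
size-s panel is the top s, so panels nest by construction. The rank
statistic itself is an open choice (the source protocol says only that
panels followed the GWAS); ascending p is the common reading.

## Kinship, weights, REML

`vanRadenGrm()` is VanRaden method 1 on dosages centered at twice the
allele frequency; `weightedGrm()` is the standard weighted form
`Z D Z' / Σ w_j 2f_j(1−f_j)`, which reduces to the plain matrix at uniform
weights, treats a zero weight exactly like dropping the locus, and is
invariant to rescaling all weights. Within the weighted (prior) set,
weights are proportional to per-SNP variance explained and rescaled so the
set's share of the heterozygosity-weighted total equals ω (default 0.7);
the remainder is shared uniformly. The proportionality rule is the package's
resolution of an underdetermined description ("weights based on the
percentage of phenotypic variance"); ω per trait versus global is likewise
surfaced as an argument rather than asserted.

`remlH2()` is single-component AI-REML with analytic average-information
updates, step-halving when an AI step leaves the parameter space, an EM
fallback, a variance floor of 1e-8·Var(y), and convergence at
|Δlog L| < 1e-6 within 100 iterations. One eigendecomposition of G makes
every iteration O(n). The implementation was cross-checked against an
independent dense-matrix REML maximized by `optim` (agreement to 1e-5 in h²
per dataset). One scientific caveat belongs here rather than in a footnote:
GRM-REML estimates *SNP heritability under the model in which every marker
contributes*; when the generative architecture is a sparse subset of the
panel, estimates attenuate slightly (of order 0.01 at 5% causal density).
The heritability-recovery experiments therefore use a polygenic
architecture (25% of markers causal at desk scale), which matches both the
estimator's assumptions and the biology of litter traits.

## GBLUP and the Bayesian alphabet

GBLUP solves the mixed-model equations with a GLS intercept;
`g = G(G + λI)⁻¹(yc − μ)`, λ = σ²e/σ²g, and holdout prediction uses the
G[test, train] block. The identity with kernel ridge regression on the GRM
at the same λ is enforced to 1e-8 in tests.

The five Bayesian samplers share one Gibbs core (compiled, R-RNG-driven,
hence bit-reproducible under a seed): per-locus conjugate normal updates on
centered — not standardized — dosage columns, so effects stay in dosage
units consistent with the 2f(1−f)β² variance-explained formula.
Family-specific structure: a common scaled-inverse-χ² variance (ridge);
per-locus variances with a gamma-updated scale (A); spike-slab indicators
with per-locus (B) or common (C) slab variances and a beta-updated
inclusion probability; exponential-mixture latent variances with a
gamma-updated λ² and inverse-Gaussian full conditionals (LASSO). Default
run control is 5,000 iterations, 1,000 burn-in, thinning 5 (desk runs in
the tests use shorter, checked chains); default hyperparameters follow the
usual R²-partition convention (prior mode of the marker-variance total set
to half of Var(y), df 5), with the inclusion prior mean 0.5 at effective
count 10. Since the trait is pre-corrected, the samplers carry only an
intercept — that is the pipeline contract, not an omission. Correctness
anchors: fixed-variance ridge-regression sampler versus the closed-form
ridge solution within Monte-Carlo error (batch-mean SEs); Bayes C with
inclusion forced on versus the ridge sampler; null data shrinking all
posterior means to zero; variance bookkeeping σ²e + Var(fitted) ≈ Var(y).

## Machine-learning regressors on kinship features

All five regressors consume GRM rows restricted to the training columns
(the "relationship profile" representation; raw dosages remain available to
compare). The CART grower uses exact midpoint thresholds with weighted
variance-reduction splits, deterministic tie-breaks (first feature, smallest
threshold) and an optional quantile pre-binning mode; the forest adds
bootstrap bagging and per-split feature subsampling; boosting is stagewise
least-squares with shrinkage, and its GOSS variant keeps the top-a fraction
of samples by absolute residual plus an upweighted random b fraction —
with a = 1 the code path consumes no randomness and is bit-identical to
plain boosting. Exclusive feature bundling is deliberately omitted: it
targets sparse one-hot features, and kinship features are dense.
AdaBoost.R2 follows Drucker: normalized per-round losses (linear by
default; square/exponential available), error rate ε = L̄/(1 − L̄), a
multiplicative weight update, early stop at L̄ ≥ 0.5, and the weighted
median (infimum form, smallest prediction whose cumulative weight reaches
half) as the combination rule.

## Evaluation harness

Accuracy is the Pearson correlation; fivefold CV partitions 400 training
animals into folds of 80 under a seed, aggregates by the unweighted fold
mean, and flags constant-truth folds rather than scoring them. The
hyperparameter tuner is a Gaussian-process surrogate (Matérn-5/2 on the
unit cube, one marginal-likelihood-fitted lengthscale, expected-improvement
acquisition over a random candidate set, failures recorded and never
proposed as best); 300 iterations is the paper-scale default, desk runs use
20–50. The ANOVA utilities expose both the raw-vector one-way analysis
(through `stats::aov`) and the completion of a published table from its
primary sums of squares and degrees of freedom, including the critical F at
α = 0.05.

Two protocol decisions shape the sweep (`panelSweep()`):

* **Panel ranking uses the full cohort**, holdout included, as in the
  source protocol (the GWAS ran on all 515 animals). The holdout is
  independent of model *fitting*, not of panel *selection*. This is what
  makes cross-validation and independent-test accuracy series track each
  other across panel sizes; it also means both are inflated by marker
  selection, which is precisely the regime in which accuracies far above
  √h² arise for traits of this heritability.
* **The candidate-herd scenario** — the protocol's stated purpose for the
  independent test — is exercised separately: markers ranked on the
  training animals only, hyperparameters tuned by CV and frozen, one shot
  at the untouched holdout. There the holdout falls below the CV estimate,
  as it must when the CV estimate rides on selection the holdout never saw.

The trend experiments at desk scale use panels of 1,000–9,000 SNPs out of
10,000 (standing in for 100k–900k out of millions), 4–6 replicates, GBLUP
as the sweep method, and the tuned kernel-ridge protocol for the
independent-test direction; the accuracy-versus-panel-size curve rises and
then falls, and weighting stabilizes the largest panels (lower variance of
accuracy across the top three sizes in most replicates). The independent
test refits on all 400 training animals before the holdout shot, the
default reading of a protocol that does not say whether fold models were
reused.

## Problem sizes and runtime

The test suite simulates everything it needs: heritability recovery at
n = 515 with 1,200 markers and 50 replicates per truth; QTL recovery at
n = 400, 500 markers, 20 replicates; calibration at 10,000 null markers and
300 small-matrix spectra; the sweep at the sizes above. The full suite runs
in a few minutes on one CPU, and `scripts/acceptance.R` in about two.

## Known limitations

* The genotype generator's LD is block-structured and stationary; results
  that depend on realistic long-range LD decay are out of reach.
* Successive Tracy–Widom tests beyond the leading component are
  conservative; if exhaustive structure testing matters, permutation nulls
  are the honest alternative.
* The Bayesian samplers implement the standard conjugate updates but not
  analytical marginal likelihoods or multi-trait extensions.
* Real-data accuracy levels are not reproduced — without the original
  genotypes only trend-level statements are checkable, and the simulation
  makes selection-inflation (shared marker selection between CV and
  holdout) explicit rather than hiding it.
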