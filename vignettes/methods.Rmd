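---
title: "Partitioning protein-level variance across genetic and epigenetic factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning protein-level variance across genetic and epigenetic factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Circulating inflammatory proteins sit at the interface of genetic regulation,
epigenetic state and disease. Individual protein levels are shaped jointly by
common genetic variants (pQTLs), DNA-methylation differences at CpG sites, and
environmental exposures such as smoking. `protarch` implements a complete
analysis path for asking, for each protein: *how much of the inter-individual
variation is attributable to genetics, how much to methylation, which
individual markers drive those contributions, and do the associations carry
causal information about disease?*

The package is organised around one central model — a grouped spike-and-slab
Gaussian-mixture regression fitted by Gibbs sampling (`bayesmix()`) — with
marginal association scans, cross-method triangulation, colocalisation,
Mendelian randomisation and gene-set enrichment as the surrounding stages, and
a synthetic-cohort generator that provides ground truth for validating all of
them.

## Phenotype preparation

Protein abundances from multiplex panels arrive on an arbitrary log-like
scale with detection-limit censoring. The preparation pipeline is:

1. **Limit-of-detection filtering** (`lod_filter()`): a protein is removed
   when *strictly more than* 40% of samples fall below the assay's lowest
   limit of detection. The strict inequality matters at the boundary: a
   protein with exactly 40% below-LOD samples is retained.
2. **Rank-based inverse normalisation** (`rank_inverse_normal()`): values are
   replaced by normal quantiles at `(rank - 0.5)/n`. Ties receive average
   ranks; missing values propagate. Because only ranks enter, the transform
   is exactly invariant to any strictly monotone rescaling of the raw data —
   which is why the synthetic generator's Gaussian abundance noise is
   immaterial. The Blom offset `(rank - 3/8)/(n + 1/4)` is selectable; the
   half offset is the default because it maps the median of an odd-length
   sample to exactly zero.
3. **Covariate residualisation** (`residualize()`): OLS residuals on age,
   sex, ancestry principal components and array plate (plate as fixed
   indicator contrasts), re-scaled to mean 0, variance 1. Perfect fits and
   collinear covariates raise errors rather than emitting NaNs.

## Marginal scans and conditional analysis

`ols_scan()` performs per-marker least squares with optional covariates,
reporting effect per allele (genotypes enter as 0/1/2 dosages) or per SD of
methylation (probes are standardised). p-values come from the t distribution
at the scan's residual degrees of freedom and are clamped at 1e-320 to avoid
underflow to zero. Significance thresholds divide genome-wide levels by the
number of phenotypes scanned: 5.0e-8/70 = 7.14e-10 for SNPs and
3.6e-8/70 = 5.14e-10 for CpGs (`bonferroni_threshold()`).

`stepwise_conditional()` implements forward selection at a fixed threshold:
scan the phenotype residualised on the selected markers, admit the top
marker while its conditional p passes, and report effect sizes from a final
joint refit. Ties on p are broken by genomic position (lowest chromosome,
then position), which makes the output invariant to marker column order.
Selection is aborted with a diagnostic if it ever reaches half the sample
size — a symptom of pathological collinearity, not signal.

`mlm_ewas()` guards the epigenome-wide scan against cell-composition and
batch structure by fitting a methylation relatedness matrix `K = MM'/m`
(all standardised probes, candidate included) as a random effect. Variance
components are estimated once on the null model by REML through a single
eigendecomposition of `K`, then each probe is tested by GLS in the rotated
basis. This is the standard fast mixed-model strategy for omic association;
the candidate probe's own contribution to `K` is retained because probe
coordinates in synthetic data are arbitrary, so leave-one-chromosome-out
schemes would be artificial here. Setting the variance ratio `delta = Inf`
recovers OLS exactly, which the tests exploit as a reduction oracle.
`genomic_inflation()` summarises calibration as the median association
chi-squared over its null value 0.4549364.

`attenuation_percent()` quantifies confounder adjustment:
`100·(|b_unadj| - |b_adj|)/|b_unadj|`, with a sign-flip flag instead of a
percentage when adjustment reverses the effect direction.

## The grouped spike-and-slab mixture model

For phenotype `y` (standardised), fixed covariates `C` and marker groups
`X_g` (column-standardised; e.g. SNPs and CpGs):

```
y = C·gamma + sum_g X_g·beta_g + e,   e ~ N(0, sigma_e^2 I)
beta_gj = 0                with probability pi_g0        (spike)
beta_gj ~ N(0, c_gk·sigma_g^2) with probability pi_gk    (component k)
```

Component variance constants are `(0.01, 0.1)` for a stand-alone SNP run,
`(0.001, 0.01, 0.1)` for methylation, and `(0.01, 0.1, 0.2)` for the
combined run, where both groups must share a component count. By default the
constants multiply a per-group variance hyperparameter `sigma_g^2` that is
itself sampled (so the constants encode relative effect-size classes); an
absolute-variance interpretation is selectable per prior via
`mixture_prior(scale = "absolute")`. Mixture proportions get a flat
Dirichlet(1) prior; `sigma_g^2` and `sigma_e^2` get weakly informative
scaled inverse-chi-square priors (`nu0 = 0.001`, `s0^2 = 0.001`). None of
these three choices is sharply identified by the applications and all are
exposed as arguments.

The Gibbs sweep samples, in order: fixed effects from their conditional
normals (flat prior); every marker's component indicator from the
conditional posterior odds followed by its effect from the conditional
normal, visiting markers in an order re-randomised each sweep to reduce
autocorrelation; group mixture proportions from a Dirichlet; group variance
hyperparameters and the residual variance from scaled inverse-chi-square
conditionals. The default schedule is 10000 iterations, 5000 burn-in,
thinning 5 (1000 retained draws); all randomness flows from one seed, so
chains are bit-reproducible. Hyperparameters can be held fixed
(`fix = list(...)`), which the test suite uses to compare the sampler
against brute-force enumeration on a two-marker problem.

Two summaries matter downstream:

- **PIP** — the fraction of retained draws in which a marker's effect is
  non-zero; markers with PIP >= 0.95 are declared significant
  (`significant_markers()`, inclusive at the boundary).
- **Variance shares** — per retained draw, `var(X_g beta_g)/var(y)` on the
  analysis sample (the realised, sample-specific quantity rather than
  `m·E[beta^2]`, so shares remain sensibly bounded). Posterior means and
  2.5/97.5-percentile credible intervals come from `variance_partition()`.
  Per-component attribution uses the covariance decomposition
  `cov(u_gk, u_g)/var(y)`, which — unlike per-component variances — sums
  exactly to the group share within every draw.

`compare_variance_posteriors()` applies a Welch t-test to share draws from a
stand-alone versus a combined fit, the device used to ask whether adding the
other omics layer changes a group's explained variance.

## Triangulation, colocalisation and Mendelian randomisation

Hits from different methods rarely name the same variant when LD is strong,
so `triangulate()` declares a marker concordant when every method's hit set
contains it directly *or* contains a proxy with `r^2 > 0.75`, computed on
the analysis sample's dosages (no external reference panel).
`classify_cis_trans()` uses a 10 Mb window around the encoding gene's TSS,
inclusive at the boundary because the convention is "within 10 Mb".

`coloc_posteriors()` assembles per-SNP Wakefield log-ABFs into the
five-hypothesis posterior (no causal variant; trait-1 only; trait-2 only;
distinct variants; shared variant) with priors `p1 = p2 = 1e-4`,
`p12 = 1e-5` and a quantitative-trait effect prior SD of 0.15 — the
conventional defaults, recorded in the result object. All accumulation is
in log space with log-sum-exp, so `|z|` up to 50 stays finite. PP >= 0.95
is read as strong evidence. Regions are extracted with a 200 kb flank on
each side of the sentinel variant (`extract_region()`).

For MR, instruments are LD-pruned greedily in p-value order so the sentinel
always survives (`ld_prune()`, kept pairs satisfy `r^2 < 0.1`).
`harmonise_sumstats()` aligns effect alleles, flipping outcome betas at
swapped-allele variants and dropping strand-ambiguous (A/T, C/G) variants —
the conservative convention when strand cannot be verified. Estimators: `wald_ratio()`
(single instrument, first-order delta-method se), `mr_ivw()` (fixed-effect
weighted regression through the origin, weights `1/se_out^2`), and
`mr_egger()` (weighted regression with intercept after orienting exposure
effects non-negative; the intercept tests directional pleiotropy).

`hypergeom_enrich()` covers over-representation of hit genes in gene-set
collections with the upper-tail convention `P(X >= k)` and an explicitly
supplied universe.

## The synthetic-cohort generator

The generator exists to give every stage a case with known truth, matching
the statistical structure the analysis assumes:

- **Genotypes**: haplotype-pair binomials with first-order Markov copying
  inside LD blocks (`ld_decay` = copying probability). This is the simplest
  mechanism with tunable `r^2`, sufficient for pruning, clumping and
  proxy-linking tests; it makes no attempt at realistic human LD maps.
- **Methylation**: probe intercept + Dirichlet cell-proportion loadings +
  batch shifts + designated smoking-reactive probes + Gaussian noise, on an
  unbounded M-value-like scale. Downstream stages standardise columns, so
  no [0,1] beta-value constraint is imposed. Smoking can act on both probes
  and the protein, generating the confounding that the attenuation analysis
  detects.
- **Proteins**: causal SNPs/CpGs drawn with mixture-class effect sizes, then
  rescaled on *realised* component variances so the recorded variance
  fractions match their targets by construction (the recorded truth, not
  the nominal target, is the oracle for recovery tests); the phenotype is
  standardised to variance 1.
- **Summary-statistic pairs**: regional z-scores from
  `z ~ MVN(sqrt(n)·R·b, R)` over a simulated reference panel's correlation
  matrix, under shared-causal, distinct-causal, one-trait-only and
  no-signal scenarios.

What the generator does *not* emulate — imputation uncertainty, probe
cross-hybridisation, assay chemistry, fine-scale human LD — bounds what
passing tests demonstrate: correctness of the statistical machinery under
its stated model, not robustness to every artefact of real cohort data.

## Problem sizes, numerical choices and limitations

Validation runs use desk-scale cohorts chosen to keep full-pipeline checks
fast while preserving the qualitative regime of the applications: variance-
share recovery uses n = 1000 with 2000 SNPs + 2000 CpGs and true shares
0.30/0.20 across 20 seeds; single-variant recovery uses n = 876 with a SNP
explaining 36% of variance. For these sizes a 2500-iteration chain with 500
burn-in and no thinning (2000 retained draws) mixes well — the posterior is
dominated by a handful of strong effects — whereas the 10000/5000/5 default
remains appropriate for larger marker panels.

Numerical conventions worth knowing: p-values clamp at 1e-320; monomorphic
markers are skipped with a log entry; degenerate inputs (all-constant
phenotypes, rank-deficient covariates, zero residual variance) raise typed
errors; stepwise ties break by genomic position; the sampler validates that
group columns are standardised to |mean| <= 1e-6 and |var - 1| <= 1e-4
rather than silently rescaling.

Known limitations: single-chain inference (no cross-chain convergence
diagnostics beyond the retained-draw count); the mixed model estimates
variance components once on the null rather than per probe; colocalisation
assumes at most one causal variant per trait per region; MR supports Wald,
IVW and Egger but not median or multi-variable estimators.
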