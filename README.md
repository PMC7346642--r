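# protarch

Genetic and epigenetic architecture of plasma protein levels.

Circulating inflammatory proteins are shaped jointly by common genetic
variants (pQTLs), DNA methylation at CpG sites, and exposures such as
smoking. `protarch` implements an end-to-end analysis of that architecture
for quantitative protein panels:

- **Phenotype preparation** — limit-of-detection filtering (proteins with
  \>40% of samples below LOD removed), rank-based inverse normalisation
  through `qnorm((rank − ½)/n)`, and covariate residualisation to
  standardised phenotypes.
- **Marginal scans** — per-marker OLS genome-/epigenome-wide association
  with Bonferroni thresholds `5.0e-8/70 = 7.14e-10` (SNPs) and
  `3.6e-8/70 = 5.14e-10` (CpGs), stepwise conditional analysis with joint
  refitting, a mixed-model EWAS with a methylation relatedness matrix
  fitted by REML, genomic-inflation lambdas and confounder-attenuation
  percentages.
- **The core model** — a grouped spike-and-slab Gaussian-mixture regression
  fitted by Gibbs sampling:

  ```
  y = Cγ + Σ_g X_g β_g + e,          e ~ N(0, σ²_e I)
  β_gj = 0                with prob π_g0            (spike)
  β_gj ~ N(0, c_gk σ²_g)  with prob π_gk            (slab component k)
  ```

  with component constants (0.01, 0.1) for SNPs, (0.001, 0.01, 0.1) for
  CpGs, (0.01, 0.1, 0.2) for combined runs; Dirichlet priors on π and
  scaled inverse-χ² conditionals for σ²_g, σ²_e. Each retained draw records
  per-marker inclusion (PIP; ≥ 0.95 declared significant) and per-group
  realised variance shares `var(X_g β_g)/var(y)` with 95% credible
  intervals and per-component attribution — i.e. SNP-based heritability and
  methylation-explained variance, jointly.
- **Triangulation** — cross-method concordance of hits directly or through
  LD proxies (r² \> 0.75), cis/trans classification at 10 Mb from the
  encoding gene's TSS, effect-size correlations with Fisher-z intervals.
- **Causal follow-up** — Wakefield-ABF colocalisation over ±200 kb regions
  with the five-hypothesis posterior (PP0–PP4, defaults p1 = p2 = 1e-4,
  p12 = 1e-5), LD pruning at r² \< 0.1, and two-sample Mendelian
  randomisation (Wald ratio, fixed-effect IVW, MR-Egger with pleiotropy
  intercept).
- **Enrichment** — upper-tail hypergeometric over-representation of hit
  genes against GMT gene-set collections with an explicit universe.
- **Synthetic cohorts** — generators for LD-blocked genotypes, structured
  methylation (cell proportions, batches, smoking-reactive probes) and
  protein phenotypes with *recorded ground truth*, used throughout the test
  suite as recovery oracles.

## Worked example

Simulate a cohort of 876 individuals with 500 SNPs and 500 CpGs where
genetics explains 30% and methylation 20% of protein variance, then fit the
combined model:

```r
library(protarch)

g   <- simulate_genotypes(876, 500, seed = 7)
me  <- simulate_methylation(876, 500, seed = 8)
sim <- simulate_proteins(g, me$methylation, me$covariates,
         arch = protein_architecture(n_causal_snps = 10, n_causal_cpgs = 10,
                                     h2_genetic = 0.30, h2_methylation = 0.20),
         seed = 9)

fit <- bayesmix(list(snp = standardize_columns(g$dosages),
                     cpg = standardize_columns(me$methylation$values)),
                sim$protein,
                covariates = me$covariates[, c("smoking", "cell1", "cell2")],
                priors = mixture_prior(c(0.01, 0.1, 0.2)),
                chain = chain_config(2500, 500, 1, seed = 10))
fit
#> Grouped spike-and-slab mixture fit
#>   n = 876 ; groups: snp (500 markers), cpg (500 markers)
#>   retained draws: 2000 (2500 iterations, 500 burn-in, thin 1, seed 10)
#>   posterior variance shares:
#>     snp: 0.279 [0.227, 0.331]
#>     cpg: 0.238 [0.190, 0.288]
```

The posterior mean shares bracket the realised truths recorded by the
generator (0.296 genetic, 0.197 methylation; both inside the 95% credible
intervals). `summary(fit)` adds the significant markers:

```r
summary(fit)
#> Variance partition (posterior mean share and 95% credible interval):
#>  group mean_share  ci_lower  ci_upper   share_c1   share_c2  share_c3
#>    snp  0.2791419 0.2270685 0.3311636 0.02105434 0.09406041 0.1640272
#>    cpg  0.2380975 0.1902141 0.2879137 0.01810023 0.07271978 0.1472775
#>
#> Markers with PIP >= 0.95 : 10
#>  group        id   pip  beta_mean    beta_sd
#>    snp  snp00083 1.000  0.2765835 0.03090495
#>    snp  snp00140 1.000  0.1707029 0.02507970
#>    ...
```

The `share_c*` columns attribute each group's explained variance to the
mixture's effect-size classes (small/medium/large); within every posterior
draw they sum exactly to the group share. The ten PIP ≥ 0.95 markers are
the planted causal markers with the largest effects; the remaining planted
effects are too small to be individually resolved at this sample size but
still contribute to the shares.

Downstream, `triangulate()` checks hits across methods, and for a sentinel
pQTL:

```r
sp <- simulate_summary_pair("shared_causal", n_snps = 500, seed = 5)
coloc_posteriors(sp$stats1, sp$stats2)
#> Colocalisation over 500 SNPs (p1 = 1e-04 , p2 = 1e-04 , p12 = 1e-05 )
#>    PP0    PP1    PP2    PP3    PP4
#> 0.0000 0.0000 0.0000 0.0000 1.0000
#> Modal hypothesis: PP4 (strong evidence, PP >= 0.95)
```

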