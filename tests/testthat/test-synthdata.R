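test_that("genotype generator honours allele frequency and LD settings", {
  g <- simulate_genotypes(10000, 1, maf_range = c(0.5, 0.5), seed = 1)
  expect_true(abs(mean(g$dosages) - 1) < 0.03)
  expect_true(all(g$dosages %in% 0:2))

  ## perfect copying makes a block a set of exact proxies
  g1 <- simulate_genotypes(200, 8, ld_block_size = 8, ld_decay = 1, seed = 2)
  r2 <- cor(g1$dosages)^2
  expect_true(all(abs(r2 - 1) < 1e-12))

  ## no copying: mean off-diagonal r2 on the null 1/(n-1) scale, compared to
  ## a permutation null built by shuffling each column independently
  set.seed(3)
  g0 <- simulate_genotypes(400, 40, ld_decay = 0, seed = 3)
  r2_obs <- cor(g0$dosages)^2
  obs <- mean(r2_obs[upper.tri(r2_obs)])
  perm <- replicate(25, {
    shuf <- apply(g0$dosages, 2L, sample)
    rp <- cor(shuf)^2
    mean(rp[upper.tri(rp)])
  })
  expect_gt(obs / mean(perm), 0.5)
  expect_lt(obs / mean(perm), 2)

  ## map invariants
  expect_false(is.unsorted(g0$snp_map$pos, strictly = TRUE))
  expect_true(all(abs(pmin(colMeans(g0$dosages) / 2,
                           1 - colMeans(g0$dosages) / 2) - g0$snp_map$maf) < 1e-12))
  expect_error(simulate_genotypes(10, 5, maf_range = c(0, 0.6)), "maf_range")
  expect_error(simulate_genotypes(1, 5), "`n`")
})

test_that("generators are bit-reproducible for a fixed seed", {
  a <- simulate_genotypes(50, 20, seed = 7)
  b <- simulate_genotypes(50, 20, seed = 7)
  expect_identical(a, b)
  ma <- simulate_methylation(30, 15, seed = 7)
  mb <- simulate_methylation(30, 15, seed = 7)
  expect_identical(ma, mb)
})

test_that("methylation generator builds simplex cell proportions and a recoverable smoking effect", {
  sim <- simulate_methylation(500, 50, smoking_prevalence = 0.4,
                              n_smoking_probes = 3, smoking_effect = -2, seed = 11)
  props <- as.matrix(sim$covariates[, grep("^cell", names(sim$covariates))])
  expect_true(all(abs(rowSums(props) - 1) < 1e-12))
  expect_false(anyNA(sim$methylation$values))
  expect_true(all(is.finite(sim$methylation$values)))

  ## OLS on a smoking-reactive probe recovers the planted effect
  probe <- sim$methylation$values[, sim$methylation$smoking_probes[1]]
  fit <- summary(lm(probe ~ sim$covariates$smoking))$coefficients
  expect_lt(abs(fit[2, 1] - (-2)), 3 * fit[2, 2])

  expect_error(simulate_methylation(10, 5, smoking_prevalence = 1.5),
               "smoking_prevalence")
})

test_that("structureless methylation behaves as independent noise", {
  sim <- simulate_methylation(300, 30, n_cell_types = 1, batch_levels = 1,
                              n_smoking_probes = 0, seed = 12)
  r <- cor(sim$methylation$values)
  offdiag <- r[upper.tri(r)]
  ## null correlations have sd ~ 1/sqrt(n); none should be extreme
  expect_lt(max(abs(offdiag)), 6 / sqrt(300))
  expect_lt(abs(mean(offdiag^2) * 299 - 1), 0.5)
})

test_that("protein simulation hits its variance-share targets by construction", {
  g <- simulate_genotypes(800, 300, seed = 21)
  me <- simulate_methylation(800, 300, seed = 22)

  sim <- simulate_proteins(g, me$methylation, me$covariates,
                           arch = protein_architecture(n_causal_snps = 15,
                                                       n_causal_cpgs = 10,
                                                       h2_genetic = 0.3,
                                                       h2_methylation = 0.2),
                           seed = 23)
  expect_lt(abs(var(sim$protein) - 1), 1e-10)
  expect_lt(abs(sim$truth$true_h2_genetic - 0.3), 0.02)
  expect_lt(abs(sim$truth$true_h2_methylation - 0.2), 0.02)
  expect_true(all(sim$truth$causal_snp_ids %in% g$snp_map$snp_id))
  expect_true(all(sim$truth$causal_cpg_ids %in% me$methylation$cpg_map$probe_id))

  ## recorded effects reproduce the recorded genetic share exactly
  Xc <- standardize_columns(g$dosages[, sim$truth$causal_snp_ids, drop = FALSE])
  gc <- drop(Xc %*% sim$truth$snp_effects)
  expect_lt(abs(var(gc) / var(sim$protein) - sim$truth$true_h2_genetic), 1e-10)
})

test_that("null architecture yields a phenotype uncorrelated with all markers", {
  g <- simulate_genotypes(600, 400, seed = 31)
  sim <- simulate_proteins(g, arch = protein_architecture(h2_genetic = 0,
                                                          h2_methylation = 0),
                           seed = 32)
  r <- abs(cor(g$dosages, sim$protein))
  ## Bonferroni-style bound on the maximum null correlation over 400 markers
  expect_lt(max(r), qnorm(1 - 0.01 / (2 * 400)) / sqrt(600 - 2))
})

test_that("single strong SNP reaches its planted marginal r-squared", {
  g <- simulate_genotypes(1000, 50, seed = 41)
  sim <- simulate_proteins(g, arch = protein_architecture(n_causal_snps = 1,
                                                          h2_genetic = 0.36,
                                                          h2_methylation = 0),
                           seed = 42)
  r2 <- cor(g$dosages[, sim$truth$causal_snp_ids], sim$protein)^2
  expect_lt(abs(r2 - 0.36), 0.04)
})

test_that("misaligned sample ids are rejected", {
  g <- simulate_genotypes(50, 10, seed = 51)
  me <- simulate_methylation(50, 10, seed = 52)
  rownames(me$methylation$values) <- rev(rownames(me$methylation$values))
  expect_error(simulate_proteins(g, me$methylation, me$covariates, seed = 53),
               "not aligned")
})

test_that("doubling the sample size shrinks causal-marker standard errors as 1/sqrt(n)", {
  ratios <- vapply(1:10, function(r) {
    ses <- vapply(c(500, 2000), function(n) {
      g <- simulate_genotypes(n, 20, seed = 600 + 7 * r + n)
      sim <- simulate_proteins(g, arch = protein_architecture(
        n_causal_snps = 1, h2_genetic = 0.2, h2_methylation = 0), seed = 700 + r + n)
      scan <- ols_scan(g, sim$protein)
      scan$se[scan$id == sim$truth$causal_snp_ids]
    }, 0)
    ses[1] / ses[2]
  }, 0)
  ## n grows 4x, so se shrinks ~2x; per doubling that is sqrt(2)
  expect_gt(mean(sqrt(ratios)), 1.25)
  expect_lt(mean(sqrt(ratios)), 1.6)
})

test_that("summary-pair generator produces consistent regional statistics", {
  ## independent SNPs so the z-scores are iid and the KS test is valid
  ns <- simulate_summary_pair("no_signal", n_snps = 500, ld_decay = 0, seed = 61)
  z <- ns$stats1$beta / ns$stats1$se
  expect_gt(ks.test(z, "pnorm")$p.value, 0.01)
  expect_true(all(abs(ns$stats1$beta / ns$stats1$se -
                        qnorm(ns$stats1$p / 2, lower.tail = FALSE) *
                        sign(ns$stats1$beta)) < 1e-6))

  sh <- simulate_summary_pair("shared_causal", n_snps = 200, seed = 62)
  expect_identical(sh$causal$trait1, sh$causal$trait2)
  i <- match(sh$causal$trait1, sh$stats1$id)
  expect_gt(abs(sh$stats1$beta[i] / sh$stats1$se[i]), 6)

  dc <- simulate_summary_pair("distinct_causal", n_snps = 200, seed = 63)
  r2 <- dc$ld[match(dc$causal$trait1, dc$stats1$id),
              match(dc$causal$trait2, dc$stats1$id)]^2
  expect_lt(r2, 0.05)
  expect_error(simulate_summary_pair("nope"), "arg")
})

test_that("architecture round-trips through JSON unchanged", {
  g <- simulate_genotypes(100, 30, seed = 71)
  me <- simulate_methylation(100, 30, seed = 72)
  sim <- simulate_proteins(g, me$methylation, me$covariates,
                           arch = protein_architecture(n_causal_snps = 5,
                                                       n_causal_cpgs = 5,
                                                       confounder_effects = c(smoking = 0.2)),
                           seed = 73)
  path <- withr::local_tempfile(fileext = ".json")
  write_architecture(sim$truth, path)
  back <- read_architecture(path)
  expect_identical(back$causal_snp_ids, sim$truth$causal_snp_ids)
  expect_identical(back$causal_cpg_ids, sim$truth$causal_cpg_ids)
  expect_equal(back$snp_effects, sim$truth$snp_effects)
  expect_equal(back$cpg_effects, sim$truth$cpg_effects)
  expect_equal(back$true_h2_genetic, sim$truth$true_h2_genetic)
  expect_equal(back$true_h2_methylation, sim$truth$true_h2_methylation)
  expect_equal(back$confounder_effects, sim$truth$confounder_effects)
  expect_equal(back$seed, sim$truth$seed)
})
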