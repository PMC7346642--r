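fit_small <- function(y, X, seed = 1, n_iter = 1500, burn_in = 300,
                      priors = mixture_prior(c(0.01, 0.1)), ...) {
  bayesmix(list(snp = X), y, priors = priors,
           chain = chain_config(n_iter, burn_in, 1, seed = seed), ...)
}

test_that("chain configuration arithmetic and validation", {
  cc <- chain_config(10000, 5000, 5, seed = 1)
  expect_identical(cc$n_retained, 1000L)
  expect_error(chain_config(1000, 1000, 5), "burn_in")
  expect_error(mixture_prior(c(0.1, 0.01)), "increasing")
  expect_error(mixture_prior(c(0.01, 0.1), dirichlet = c(1, 1)), "concentration")
})

test_that("non-standardised marker groups are rejected", {
  set.seed(2)
  X <- matrix(rbinom(200, 2, 0.3), 50, 4)
  expect_error(bayesmix(list(g = X), rnorm(50)), "standardised")
})

test_that("identical seeds give bit-identical chains", {
  set.seed(3)
  X <- standardize_columns(matrix(rnorm(100 * 20), 100, 20))
  y <- rnorm(100)
  f1 <- fit_small(y, X, seed = 42)
  f2 <- fit_small(y, X, seed = 42)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$marker, f2$marker)
  f3 <- fit_small(y, X, seed = 43)
  expect_false(identical(f1$draws$share, f3$draws$share))
})

test_that("posterior summaries satisfy their structural invariants", {
  g <- simulate_genotypes(300, 100, seed = 4)
  sim <- simulate_proteins(g, arch = protein_architecture(
    n_causal_snps = 5, h2_genetic = 0.4, h2_methylation = 0), seed = 5)
  fit <- fit_small(sim$protein, standardize_columns(g$dosages), seed = 6)

  expect_true(all(fit$marker$pip >= 0 & fit$marker$pip <= 1))
  vp <- variance_partition(fit)
  expect_true(vp$ci_lower <= vp$mean_share && vp$mean_share <= vp$ci_upper)
  expect_true(all(fit$draws$share >= 0 & fit$draws$share <= 1))

  ## pi draws are probability vectors
  pis <- fit$draws$pi
  expect_true(all(abs(rowSums(pis) - 1) < 1e-12))

  ## component attribution sums to the group share within every draw
  tot <- rowSums(fit$draws$comp_share)
  expect_true(all(abs(tot - fit$draws$share[, 1]) < 1e-10))

  ## fitted + residuals reconstruct the phenotype
  expect_equal(fitted(fit) + residuals(fit), fit$y, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("PIP thresholding uses >= semantics", {
  g <- simulate_genotypes(200, 30, seed = 7)
  sim <- simulate_proteins(g, arch = protein_architecture(
    n_causal_snps = 1, h2_genetic = 0.3, h2_methylation = 0), seed = 8)
  fit <- fit_small(sim$protein, standardize_columns(g$dosages), seed = 9)
  fake <- fit
  fake$marker$pip <- rep(0.95, nrow(fake$marker))
  expect_equal(nrow(significant_markers(fake, 0.95)), nrow(fake$marker))
  fake$marker$pip <- rep(0, nrow(fake$marker))
  expect_equal(nrow(significant_markers(fake, 0.95)), 0)
  expect_equal(nrow(significant_markers(fake, 0)), nrow(fake$marker))
})

test_that("null data give no significant markers and a near-zero share", {
  set.seed(10)
  X <- standardize_columns(matrix(rnorm(1000 * 1000), 1000, 1000))
  y <- rnorm(1000)
  fit <- fit_small(y, X, seed = 11)
  expect_true(all(fit$marker$pip < 0.95))
  vp <- variance_partition(fit)
  expect_lt(vp$ci_lower, 0.05)
  expect_lt(vp$mean_share, 0.1)
})

test_that("two-marker posterior inclusion matches brute-force enumeration", {
  set.seed(12)
  n <- 30
  X <- standardize_columns(matrix(rnorm(n * 2) + rnorm(n), n, 2))
  colnames(X) <- c("m1", "m2")
  b_true <- c(0.6, 0)
  y <- drop(X %*% b_true) + rnorm(n, 0, 1)
  y <- y - mean(y)
  v <- 0.5; sigma_e <- 1

  ## oracle: marginal likelihood of each spike/slab configuration times the
  ## Dirichlet-multinomial prior weight, flat Dirichlet(1, 1)
  configs <- list(integer(0), 1L, 2L, 1:2)
  ll <- vapply(configs, function(S) logml_config(y, X, S, v, sigma_e), 0)
  lprior <- vapply(configs, function(S) {
    j <- length(S); lgamma(1 + j) + lgamma(1 + 2 - j) - lgamma(4) + lgamma(2)
  }, 0)
  w <- exp(ll + lprior - max(ll + lprior))
  w <- w / sum(w)
  pip_oracle <- c(sum(w[c(2, 4)]), sum(w[c(3, 4)]))

  fit <- bayesmix(list(g = X), y, covariates = NULL, intercept = FALSE,
                  priors = mixture_prior(1, scale = "relative"),
                  chain = chain_config(51000, 1000, 1, seed = 13),
                  fix = list(sigma_g = v, sigma_e = sigma_e))
  expect_lt(max(abs(fit$marker$pip - pip_oracle)), 0.03)
})

test_that("swapping group order leaves the variance partition unchanged", {
  g <- simulate_genotypes(500, 300, seed = 14)
  me <- simulate_methylation(500, 300, seed = 15)
  sim <- simulate_proteins(g, me$methylation, me$covariates,
                           arch = protein_architecture(n_causal_snps = 10,
                                                       n_causal_cpgs = 10,
                                                       h2_genetic = 0.3,
                                                       h2_methylation = 0.2),
                           seed = 16)
  Xs <- standardize_columns(g$dosages)
  Xm <- standardize_columns(me$methylation$values)
  pr <- mixture_prior(c(0.01, 0.1, 0.2))
  f_ab <- bayesmix(list(snp = Xs, cpg = Xm), sim$protein, priors = pr,
                   chain = chain_config(1500, 300, 1, seed = 17))
  f_ba <- bayesmix(list(cpg = Xm, snp = Xs), sim$protein, priors = pr,
                   chain = chain_config(1500, 300, 1, seed = 17))
  va <- variance_partition(f_ab); vb <- variance_partition(f_ba)
  expect_lt(abs(va$mean_share[va$group == "snp"] -
                  vb$mean_share[vb$group == "snp"]), 0.02)
  expect_lt(abs(va$mean_share[va$group == "cpg"] -
                  vb$mean_share[vb$group == "cpg"]), 0.02)
})

test_that("methylation share is stable when independent genetics join the model", {
  hits <- 0L
  for (r in 1:5) {
    g <- simulate_genotypes(500, 300, seed = 20 + r)
    me <- simulate_methylation(500, 300, seed = 40 + r)
    sim <- simulate_proteins(g, me$methylation, me$covariates,
                             arch = protein_architecture(n_causal_snps = 8,
                                                         n_causal_cpgs = 8,
                                                         h2_genetic = 0.25,
                                                         h2_methylation = 0.25),
                             seed = 60 + r)
    Xm <- standardize_columns(me$methylation$values)
    Xs <- standardize_columns(g$dosages)
    pr <- mixture_prior(c(0.01, 0.1, 0.2))
    f_alone <- bayesmix(list(cpg = Xm), sim$protein, priors = pr,
                        chain = chain_config(1200, 200, 1, seed = 80 + r))
    f_comb <- bayesmix(list(snp = Xs, cpg = Xm), sim$protein, priors = pr,
                       chain = chain_config(1200, 200, 1, seed = 80 + r))
    sa <- variance_partition(f_alone)$mean_share
    sc <- variance_partition(f_comb)
    if (abs(sa - sc$mean_share[sc$group == "cpg"]) < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("posterior draw vectors can be compared by Welch t-test", {
  set.seed(30)
  a <- rnorm(200, 0.3, 0.05)
  expect_equal(compare_variance_posteriors(a, a)$p, 1)
  expect_equal(compare_variance_posteriors(a, a)$t, 0)
  b <- a + 5 * sd(a)
  expect_lt(compare_variance_posteriors(a, b)$p, 1e-6)
  expect_error(compare_variance_posteriors(a[1:10], a), "at least 30")

  ## degenerate equal constants
  z <- rep(0.2, 50)
  expect_equal(compare_variance_posteriors(z, z)$p, 1)

  ## calibration: independent same-distribution draws give uniform p
  ps <- replicate(200, {
    compare_variance_posteriors(rnorm(50, 0.3, 0.05), rnorm(50, 0.3, 0.05))$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("identical draw vectors through t.test edge give t = 0, p = 1", {
  a <- rnorm(50)
  res <- compare_variance_posteriors(a, a)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
})
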