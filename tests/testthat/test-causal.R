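test_that("region extraction keeps the inclusive flanked window", {
  stats <- make_sumstats(paste0("s", 1:9), beta = rep(0, 9), se = rep(0.1, 9),
                         pos = c(99999, 100000, 200000, 300000, 400000,
                                 500000, 500001, 600000, 700000))
  reg <- extract_region(stats, "1", 300000, 200000)
  expect_setequal(reg$pos, c(100000, 200000, 300000, 400000, 500000))
  ## flank 0 keeps only the centre SNP
  expect_identical(extract_region(stats, "1", 300000, 0)$pos, 300000L)
  expect_error(extract_region(stats, "2", 300000, 200000), "no SNPs")
})

test_that("Wakefield log-ABF matches direct numerical integration", {
  ## oracle: log of the ratio of the two marginal likelihoods by quadrature
  quad_labf <- function(beta, se, prior_sd) {
    num <- integrate(function(b) dnorm(beta, b, se) * dnorm(b, 0, prior_sd),
                     -Inf, Inf, rel.tol = 1e-12)$value
    log(num) - dnorm(beta, 0, se, log = TRUE)
  }
  for (case in list(c(0.5, 0.05, 0.15), c(-0.2, 0.1, 0.15), c(0.01, 0.2, 0.4))) {
    expect_equal(wakefield_abf(case[1], case[2], case[3]),
                 quad_labf(case[1], case[2], case[3]), tolerance = 1e-8)
  }
  ## null z is penalised by the Occam factor; tiny prior collapses to 0
  expect_lt(wakefield_abf(0, 0.1, 0.15), 0)
  expect_lt(abs(wakefield_abf(0.5, 0.05, 1e-8)), 1e-3)
  expect_error(wakefield_abf(Inf, 0.1), "finite")
  expect_error(wakefield_abf(0.1, -1), "positive")
})

test_that("colocalisation posteriors match a direct linear-space enumeration", {
  set.seed(1)
  mk <- function(beta) make_sumstats(paste0("s", 1:10), beta, rep(0.05, 10))
  s1 <- mk(c(rnorm(9, 0, 0.02), 0.6))
  s2 <- mk(c(rnorm(9, 0, 0.02), 0.55))
  res <- coloc_posteriors(s1, s2)

  ## naive oracle, no log-space tricks (safe on a 10-SNP toy)
  a1 <- exp(wakefield_abf(s1$beta, s1$se, 0.15))
  a2 <- exp(wakefield_abf(s2$beta, s2$se, 0.15))
  w <- c(1, 1e-4 * sum(a1), 1e-4 * sum(a2),
         1e-4 * 1e-4 * (sum(a1) * sum(a2) - sum(a1 * a2)),
         1e-5 * sum(a1 * a2))
  expect_equal(unname(res$pp), w / sum(w), tolerance = 1e-10)
  expect_equal(sum(res$pp), 1, tolerance = 1e-10)
})

test_that("colocalisation is exchangeable in its two traits and stable at huge z", {
  set.seed(2)
  s1 <- make_sumstats(paste0("s", 1:50), c(rnorm(49, 0, 0.01), 0.5), rep(0.01, 50))
  s2 <- make_sumstats(paste0("s", 1:50), c(0.4, rnorm(49, 0, 0.01)), rep(0.01, 50))
  r12 <- coloc_posteriors(s1, s2)
  r21 <- coloc_posteriors(s2, s1)
  expect_equal(r12$pp[["PP1"]], r21$pp[["PP2"]], tolerance = 1e-10)
  expect_equal(r12$pp[["PP2"]], r21$pp[["PP1"]], tolerance = 1e-10)
  expect_equal(r12$pp[c("PP0", "PP3", "PP4")], r21$pp[c("PP0", "PP3", "PP4")],
               tolerance = 1e-10)

  ## |z| = 50 stays finite in log space
  sbig <- make_sumstats(c("a", "b"), c(0.5, 0), c(0.01, 0.01))
  res <- coloc_posteriors(sbig, sbig)
  expect_true(all(is.finite(res$pp)))

  ## no evidence anywhere: PP0 modal
  s0 <- make_sumstats(paste0("s", 1:30), rep(0, 30), rep(1, 30))
  expect_identical(names(which.max(coloc_posteriors(s0, s0)$pp)), "PP0")

  expect_error(coloc_posteriors(make_sumstats("a", 0, 1), make_sumstats("a", 0, 1)),
               "2 shared")
})

test_that("LD pruning keeps the sentinel and never leaves correlated pairs", {
  set.seed(3)
  n <- 1000
  a <- rbinom(n, 2, 0.3)
  b <- ifelse(runif(n) < 0.25, rbinom(n, 2, 0.3), a)   # moderate proxy of a
  c_ <- rbinom(n, 2, 0.4)                               # independent
  g <- make_genotypes(cbind(A = a, B = b, C = c_))
  r2 <- cor(g$dosages)^2
  expect_gt(r2["A", "B"], 0.1)
  expect_lt(r2["A", "C"], 0.1)

  stats <- make_sumstats(c("A", "B", "C"), beta = c(0.5, 0.4, 0.3),
                         se = rep(0.05, 3), p = c(1e-20, 1e-15, 1e-10))
  pruned <- ld_prune(stats, g, r2_max = 0.1)
  ## oracle: greedy selection recomputed from the r2 matrix in p order
  keep <- character(0)
  for (id in c("A", "B", "C"))
    if (all(r2[id, keep] < 0.1) || !length(keep)) keep <- c(keep, id)
  expect_setequal(pruned$id, keep)
  expect_true("A" %in% pruned$id)            # sentinel survives
  out_r2 <- cor(g$dosages[, pruned$id])^2
  expect_true(all(out_r2[upper.tri(out_r2)] < 0.1))

  ## perfect proxies: smaller-p one survives
  g2 <- make_genotypes(cbind(X = a, Y = a))
  st2 <- make_sumstats(c("X", "Y"), c(0.5, 0.5), c(0.05, 0.05), p = c(1e-8, 1e-4))
  expect_identical(ld_prune(st2, g2)$id, "X")

  ## mutually independent markers all survive
  g3 <- make_genotypes(cbind(P = rbinom(n, 2, .3), Q = rbinom(n, 2, .3),
                             R = rbinom(n, 2, .3)))
  st3 <- make_sumstats(c("P", "Q", "R"), c(.1, .2, .3), rep(.05, 3))
  expect_equal(nrow(ld_prune(st3, g3)), 3)
})

test_that("Wald ratio arithmetic and delta-method standard error", {
  w <- wald_ratio(0.5, 0.02, 0.1, 0.05)
  expect_equal(w$beta, 0.2)
  expect_equal(w$se, 0.1)
  expect_equal(w$n_variants, 1L)

  null <- wald_ratio(0.5, 0.02, 0, 0.05)
  expect_equal(null$beta, 0)
  expect_equal(null$p, 1)

  ## Monte-Carlo oracle for the se of the ratio with a strong instrument
  set.seed(4)
  bx <- 0.5; sx <- 0.02; by <- 0.1; sy <- 0.05   # z_exposure = 25
  draws <- rnorm(1e6, by, sy) / rnorm(1e6, bx, sx)
  expect_lt(abs(wald_ratio(bx, sx, by, sy)$se - sd(draws)) / sd(draws), 0.05)

  expect_error(wald_ratio(0, 0.02, 0.1, 0.05), "zero exposure")
})

test_that("harmonisation flips swapped alleles, drops palindromes, and is idempotent", {
  ex <- make_sumstats(c("v1", "v2", "v3", "v4"), c(0.2, 0.3, 0.4, 0.5),
                      rep(0.05, 4),
                      effect_allele = c("A", "A", "A", "A"),
                      other_allele = c("G", "G", "G", "T"))
  ou <- ex
  ou$beta <- c(0.1, -0.15, 0.2, 0.25)
  ## v2 reported on the opposite allele; v4 is strand-ambiguous (A/T)
  ou$effect_allele[2] <- "G"; ou$other_allele[2] <- "A"
  h <- harmonise_sumstats(ex, ou)
  expect_setequal(h$id, c("v1", "v2", "v3"))
  expect_equal(h$beta_outcome[h$id == "v2"], 0.15)
  expect_identical(attr(h, "flipped"), "v2")
  expect_true("v4" %in% attr(h, "dropped"))

  ## aligning an already-aligned pair changes nothing
  ou2 <- ou; ou2$effect_allele[2] <- "A"; ou2$other_allele[2] <- "G"
  ou2$beta[2] <- 0.15
  h2 <- harmonise_sumstats(ex, ou2)
  expect_equal(h$beta_outcome, h2$beta_outcome)
})

test_that("IVW recovers a planted causal effect with calibrated intervals", {
  expect_error(mr_ivw(make_sumstats("v", .2, .01), make_sumstats("v", .06, .02)),
               "wald_ratio")

  ## exact linearity gives the exact slope
  ex <- make_sumstats(paste0("v", 1:5), c(.1, .2, .3, .4, .5), rep(.01, 5))
  ou <- ex; ou$beta <- 2 * ex$beta; ou$se <- rep(.02, 5)
  expect_equal(mr_ivw(ex, ou)$beta, 2, tolerance = 1e-12)

  set.seed(5)
  cover <- 0L; ests <- numeric(50)
  for (r in 1:50) {
    bx <- rnorm(20, 0.2, 0.05); sx <- rep(0.005, 20); sy <- rep(0.02, 20)
    by <- 0.3 * bx + rnorm(20, 0, sy)
    ex <- make_sumstats(paste0("v", 1:20), bx, sx)
    ou <- ex; ou$beta <- by; ou$se <- sy
    fit <- mr_ivw(ex, ou)
    ests[r] <- fit$beta
    if (abs(fit$beta - 0.3) < qnorm(0.975) * fit$se) cover <- cover + 1L
  }
  expect_gte(cover / 50, 0.9)
  expect_lt(abs(mean(ests) - 0.3), 0.02)
})

test_that("Egger regression detects directional pleiotropy and is calibrated without it", {
  expect_error(mr_egger(make_sumstats(c("a", "b"), c(.1, .2), c(.01, .01)),
                        make_sumstats(c("a", "b"), c(.1, .2), c(.02, .02))),
               "3")

  ## exact line through the origin: zero intercept
  ex <- make_sumstats(paste0("v", 1:6), seq(.1, .6, .1), rep(.01, 6))
  ou <- ex; ou$beta <- 1.5 * ex$beta; ou$se <- rep(.02, 6)
  e0 <- mr_egger(ex, ou)
  expect_lt(abs(e0$egger_intercept), 1e-12)
  expect_equal(e0$beta, 1.5, tolerance = 1e-10)

  ## constant pleiotropy shifts the intercept and is detected
  set.seed(6)
  bx <- rnorm(30, 0.3, 0.1); sy <- rep(0.01, 30)
  by <- 0.2 + 0.4 * bx + rnorm(30, 0, sy)
  ex <- make_sumstats(paste0("v", 1:30), bx, rep(0.005, 30))
  ou <- ex; ou$beta <- by; ou$se <- sy
  ep <- mr_egger(ex, ou)
  expect_lt(abs(ep$egger_intercept - 0.2), 0.05)
  expect_lt(ep$intercept_p, 0.05)
})
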