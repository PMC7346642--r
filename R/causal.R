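#' Extract a flanked region from summary statistics
#'
#' Keeps records on the centre chromosome within `flank_bp` of the centre
#' position (boundaries inclusive): the default 200 kb flank yields a
#' 400 kb window around a sentinel pQTL.
#'
#' @param stats summary-statistics data frame.
#' @param chrom,center_pos region centre (1-based).
#' @param flank_bp flank on each side in base pairs.
#' @return subset of `stats`; error when empty (colocalisation needs SNPs).
#' @export
extract_region <- function(stats, chrom, center_pos, flank_bp = 200000) {
  check_sumstats(stats)
  check_number(flank_bp, "flank_bp", 0, Inf)
  out <- stats[stats$chrom == as.character(chrom) &
                 abs(stats$pos - center_pos) <= flank_bp, , drop = FALSE]
  if (!nrow(out)) stop_arg("no SNPs within ", flank_bp, " bp of ", chrom,
                           ":", center_pos)
  rownames(out) <- NULL
  out
}

#' Wakefield log approximate Bayes factor
#'
#' For a marginal estimate with standard error `se` and a `N(0, prior_sd^2)`
#' effect prior: with `z = beta/se`, `V = se^2`, `W = prior_sd^2` and
#' shrinkage ratio \code{r = W/(V + W)},
#' `log ABF = 0.5 * (log(1 - r) + r * z^2)`. Vectorised.
#'
#' @param beta,se marginal effect and standard error (`se > 0`).
#' @param prior_sd prior standard deviation of the true effect (> 0).
#' @return log approximate Bayes factor(s) against the null.
#' @export
wakefield_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(!is.finite(beta)) || any(!is.finite(se)) || !is.finite(prior_sd))
    stop_arg("non-finite inputs")
  if (any(se <= 0) || prior_sd <= 0) stop_arg("`se` and `prior_sd` must be positive")
  z <- beta / se
  r <- prior_sd^2 / (se^2 + prior_sd^2)
  0.5 * (log1p(-r) + r * z^2)
}

#' Colocalisation posterior probabilities for five hypotheses
#'
#' Assembles per-SNP Wakefield log-ABFs for two traits over a shared region
#' into posterior probabilities of: H0 no causal variant for either trait;
#' H1 / H2 a causal variant for trait 1 / 2 only; H3 distinct causal
#' variants; H4 a single shared causal variant. Computed entirely in log
#' space (log-sum-exp), so extreme z-scores do not overflow. SNP sets are
#' inner-joined on id; dropped SNPs are recorded.
#'
#' @param stats1,stats2 regional summary statistics for the two traits.
#' @param p1,p2 prior probability a SNP is causal for trait 1 / 2 only.
#' @param p12 prior probability a SNP is causal for both traits.
#' @param prior_sd per-trait effect prior SD (recycled to length 2);
#'   0.15 is the quantitative-trait convention.
#' @return object of class `"coloc_result"`: `pp` (named PP0..PP4 summing
#'   to 1), `n_snps`, `priors`, `dropped`.
#' @export
coloc_posteriors <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4,
                             p12 = 1e-5, prior_sd = c(0.15, 0.15)) {
  check_sumstats(stats1, "stats1"); check_sumstats(stats2, "stats2")
  prior_sd <- rep_len(prior_sd, 2L)
  shared <- intersect(stats1$id, stats2$id)
  dropped <- union(setdiff(stats1$id, shared), setdiff(stats2$id, shared))
  if (length(shared) < 2L) stop_arg("fewer than 2 shared SNPs after joining")
  s1 <- stats1[match(shared, stats1$id), ]
  s2 <- stats2[match(shared, stats2$id), ]

  l1 <- wakefield_abf(s1$beta, s1$se, prior_sd[1L])
  l2 <- wakefield_abf(s2$beta, s2$se, prior_sd[2L])

  lsum1 <- logsumexp(l1)
  lsum2 <- logsumexp(l2)
  lsum12 <- logsumexp(l1 + l2)

  lh0 <- 0
  lh1 <- log(p1) + lsum1
  lh2 <- log(p2) + lsum2
  ## sum over ordered distinct pairs = sum_i sum_j - sum_{i=j}
  la <- lsum1 + lsum2
  lh3 <- log(p1) + log(p2) + la + log1p(-exp(lsum12 - la))
  lh4 <- log(p12) + lsum12

  lw <- c(lh0, lh1, lh2, lh3, lh4)
  pp <- exp(lw - logsumexp(lw))
  structure(list(pp = setNames(pp / sum(pp), paste0("PP", 0:4)),
                 n_snps = length(shared),
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 prior_sd = prior_sd, dropped = dropped),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalisation over", x$n_snps, "SNPs (p1 =", x$priors["p1"],
      ", p2 =", x$priors["p2"], ", p12 =", x$priors["p12"], ")\n")
  print(round(x$pp, 4))
  modal <- names(x$pp)[which.max(x$pp)]
  cat("Modal hypothesis:", modal,
      if (max(x$pp) >= 0.95) "(strong evidence, PP >= 0.95)" else "", "\n")
  invisible(x)
}

#' Greedy LD pruning of summary statistics
#'
#' Orders markers by ascending p-value and keeps a marker only when its LD
#' r-squared with every already-kept marker is below `r2_max`; the sentinel
#' (smallest-p) variant therefore always survives. LD is computed from the
#' supplied genotype dosages.
#'
#' @param stats summary statistics whose markers all appear in `genotypes`.
#' @param genotypes a `"genotypes"` object.
#' @param r2_max pruning threshold (kept pairs satisfy `r2 < r2_max`).
#' @return the pruned subset of `stats`, ordered by ascending p.
#' @export
ld_prune <- function(stats, genotypes, r2_max = 0.1) {
  check_sumstats(stats)
  check_number(r2_max, "r2_max", 0, 1)
  dos <- genotypes$dosages
  missing <- setdiff(stats$id, colnames(dos))
  if (length(missing))
    stop_arg("marker(s) absent from genotype matrix: ", paste(missing, collapse = ", "))
  ord <- stats[order(stats$p), , drop = FALSE]
  kept <- character(0)
  for (id in ord$id) {
    if (all(vapply(kept, function(k) ld_r2(dos[, id], dos[, k]) < r2_max, TRUE)))
      kept <- c(kept, id)
  }
  out <- ord[ord$id %in% kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Harmonise exposure and outcome summary statistics
#'
#' Inner-joins two summary-statistic sets on marker id and aligns effect
#' alleles: where the outcome's effect/other alleles are swapped relative
#' to the exposure, the outcome beta (and allele frequency) are flipped;
#' variants with incompatible alleles and strand-ambiguous (A/T, C/G)
#' variants are dropped and logged. Applying the procedure twice is the
#' identity.
#'
#' @param exposure,outcome summary-statistics data frames.
#' @param drop_ambiguous drop A/T and C/G palindromic variants (default).
#' @return data frame with columns id, beta_exposure, se_exposure,
#'   beta_outcome, se_outcome (plus alleles); dropped ids in
#'   `attr(, "dropped")`, flipped ids in `attr(, "flipped")`.
#' @export
harmonise_sumstats <- function(exposure, outcome, drop_ambiguous = TRUE) {
  check_sumstats(exposure, "exposure"); check_sumstats(outcome, "outcome")
  shared <- intersect(exposure$id, outcome$id)
  ex <- exposure[match(shared, exposure$id), ]
  ou <- outcome[match(shared, outcome$id), ]

  ambiguous <- function(a1, a2) {
    p <- paste0(toupper(a1), toupper(a2))
    p %in% c("AT", "TA", "CG", "GC")
  }
  same <- ex$effect_allele == ou$effect_allele & ex$other_allele == ou$other_allele
  swapped <- ex$effect_allele == ou$other_allele & ex$other_allele == ou$effect_allele
  amb <- if (drop_ambiguous) ambiguous(ex$effect_allele, ex$other_allele) else FALSE
  keep <- (same | swapped) & !amb

  beta_out <- ifelse(swapped, -ou$beta, ou$beta)
  out <- data.frame(id = ex$id,
                    effect_allele = ex$effect_allele,
                    other_allele = ex$other_allele,
                    beta_exposure = ex$beta, se_exposure = ex$se,
                    beta_outcome = beta_out, se_outcome = ou$se,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- c(setdiff(union(exposure$id, outcome$id), shared),
                            shared[!keep])
  attr(out, "flipped") <- shared[swapped & keep]
  out
}

new_mr_result <- function(method, beta, se, p, n_variants,
                          egger_intercept = NULL, intercept_p = NULL) {
  structure(list(method = method, beta = beta, se = se, p = p,
                 n_variants = n_variants, egger_intercept = egger_intercept,
                 intercept_p = intercept_p), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR (%s, %d variant%s): beta %.4g, se %.4g, p %.3g\n",
              x$method, x$n_variants, if (x$n_variants > 1) "s" else "",
              x$beta, x$se, x$p))
  if (!is.null(x$egger_intercept))
    cat(sprintf("  Egger intercept %.4g (p %.3g)\n", x$egger_intercept, x$intercept_p))
  invisible(x)
}

#' Wald-ratio causal effect estimate from a single instrument
#'
#' `beta = beta_outcome / beta_exposure`; the standard error uses the
#' first-order delta method `se = se_outcome / |beta_exposure|`, with a
#' two-sided normal p-value.
#'
#' @param beta_exposure,se_exposure instrument effect on the exposure
#'   (`beta_exposure` must be non-zero).
#' @param beta_outcome,se_outcome instrument effect on the outcome.
#' @return an `"mr_result"`.
#' @export
wald_ratio <- function(beta_exposure, se_exposure, beta_outcome, se_outcome) {
  check_number(beta_exposure, "beta_exposure")
  check_number(se_outcome, "se_outcome", 0, Inf, strict_lower = TRUE)
  if (beta_exposure == 0) stop_arg("zero exposure effect: instrument undefined")
  beta <- beta_outcome / beta_exposure
  se <- se_outcome / abs(beta_exposure)
  new_mr_result("wald", beta, se, clamp_p(2 * pnorm(-abs(beta / se))), 1L)
}

#' Inverse-variance-weighted Mendelian randomisation
#'
#' Fixed-effect IVW: weighted least squares of outcome betas on exposure
#' betas through the origin with weights `1/se_outcome^2`. With a single
#' variant this reduces algebraically to the Wald ratio.
#'
#' @param exposure,outcome summary statistics, or a pre-harmonised data
#'   frame from [harmonise_sumstats()] passed as `exposure` with
#'   `outcome = NULL`.
#' @return an `"mr_result"`.
#' @export
mr_ivw <- function(exposure, outcome = NULL) {
  h <- if (is.null(outcome)) exposure else harmonise_sumstats(exposure, outcome)
  if (nrow(h) < 2L)
    stop_arg("fewer than 2 harmonised variants; use wald_ratio() for a single instrument")
  w <- 1 / h$se_outcome^2
  beta <- sum(w * h$beta_exposure * h$beta_outcome) / sum(w * h$beta_exposure^2)
  se <- sqrt(1 / sum(w * h$beta_exposure^2))
  new_mr_result("ivw", beta, se, clamp_p(2 * pnorm(-abs(beta / se))), nrow(h))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with an
#' intercept (weights `1/se_outcome^2`), after orienting every instrument
#' so its exposure effect is non-negative. The slope estimates the causal
#' effect allowing directional pleiotropy; a non-zero intercept indicates
#' directional pleiotropy.
#'
#' @inheritParams mr_ivw
#' @return an `"mr_result"` carrying `egger_intercept` and `intercept_p`.
#' @export
mr_egger <- function(exposure, outcome = NULL) {
  h <- if (is.null(outcome)) exposure else harmonise_sumstats(exposure, outcome)
  if (nrow(h) < 3L) stop_arg("MR-Egger needs at least 3 harmonised variants")
  flip <- sign(h$beta_exposure)
  flip[flip == 0] <- 1
  bx <- h$beta_exposure * flip
  by <- h$beta_outcome * flip
  fit <- lm(by ~ bx, weights = 1 / h$se_outcome^2)
  cf <- summary(fit)$coefficients
  new_mr_result("egger", cf["bx", 1L], cf["bx", 2L], clamp_p(cf["bx", 4L]),
                nrow(h), egger_intercept = cf["(Intercept)", 1L],
                intercept_p = cf["(Intercept)", 4L])
}
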