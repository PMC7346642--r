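#' Spike-and-slab mixture prior for one marker group
#'
#' Each marker's effect is a priori zero (the spike) or drawn from one of
#' several Gaussian components of increasing variance. On the default
#' `"relative"` scale the component variances are fractions multiplying the
#' group variance hyperparameter sigma_g^2 (learned from the data); on the
#' `"absolute"` scale they are used as given.
#'
#' Conventional settings: `c(0.01, 0.1)` for a stand-alone SNP analysis,
#' `c(0.001, 0.01, 0.1)` for methylation probes, and `c(0.01, 0.1, 0.2)`
#' for a combined SNP + CpG run (both groups need the same number of
#' components).
#'
#' @param component_variances strictly increasing positive numeric vector.
#' @param dirichlet Dirichlet concentration per component *including the
#'   spike* (length `length(component_variances) + 1`); default all 1
#'   (uninformative).
#' @param scale `"relative"` (default) or `"absolute"`.
#' @return object of class `"mixture_prior"`.
#' @export
mixture_prior <- function(component_variances = c(0.01, 0.1),
                          dirichlet = rep(1, length(component_variances) + 1L),
                          scale = c("relative", "absolute")) {
  scale <- match.arg(scale)
  if (!is.numeric(component_variances) || !length(component_variances) ||
      any(component_variances <= 0) || is.unsorted(component_variances, strictly = TRUE))
    stop_arg("`component_variances` must be strictly increasing and positive")
  if (length(dirichlet) != length(component_variances) + 1L || any(dirichlet <= 0))
    stop_arg("`dirichlet` needs one positive concentration per component including the spike")
  structure(list(component_variances = component_variances,
                 dirichlet = dirichlet, scale = scale),
            class = "mixture_prior")
}

#' Gibbs chain settings
#'
#' The default schedule (10000 iterations, 5000 burn-in, thinning of 5)
#' retains 1000 draws.
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in iterations discarded before recording (< `n_iter`).
#' @param thin record every `thin`-th post-burn-in iteration.
#' @param seed integer seed governing every random choice in the chain.
#' @param pip_threshold posterior-inclusion-probability significance cut-off.
#' @return object of class `"chain_config"` with the derived `n_retained`.
#' @export
chain_config <- function(n_iter = 10000L, burn_in = 5000L, thin = 5L,
                         seed = 1L, pip_threshold = 0.95) {
  n_iter <- check_count(n_iter, "n_iter")
  burn_in <- check_count(burn_in, "burn_in", min = 0L)
  thin <- check_count(thin, "thin")
  if (burn_in >= n_iter) stop_arg("`burn_in` must be smaller than `n_iter`")
  check_number(pip_threshold, "pip_threshold", 0, 1)
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = check_count(seed, "seed", min = 0L),
                 pip_threshold = pip_threshold,
                 n_retained = (n_iter - burn_in) %/% thin),
            class = "chain_config")
}

check_standardized <- function(x, name) {
  mu <- colMeans(x)
  v <- apply(x, 2L, var)
  if (any(abs(mu) > 1e-6) || any(abs(v - 1) > 1e-4))
    stop_arg("columns of group `", name, "` are not standardised ",
             "(mean 0, variance 1); see standardize_columns()")
}

#' Fit the grouped spike-and-slab Gaussian-mixture model
#'
#' Joint Bayesian regression of a standardised phenotype on one or more
#' column-standardised marker groups (e.g. a SNP block and a CpG block),
#' with per-marker spike-and-slab mixture priors, fixed-effect covariates,
#' and Gibbs sampling of all effects and hyperparameters. Each retained
#' draw records every group's realised variance share
#' `var(X_g beta_g) / var(y)` together with its attribution to the mixture
#' components, giving posterior distributions for SNP-based heritability and
#' methylation-explained variance; per-marker posterior inclusion
#' probabilities (PIPs) summarise association evidence.
#'
#' One Gibbs sweep: (1) fixed-effect coefficients from their conditional
#' normals; (2) each marker, in an order re-randomised every sweep — spike
#' vs component indicator from the conditional posterior odds, then the
#' effect from its conditional normal; (3) each group's mixture proportions
#' from a Dirichlet; (4) each group's variance hyperparameter and (5) the
#' residual variance from scaled inverse-chi-square conditionals;
#' (6) recording past burn-in on the thinning stride.
#'
#' @param groups named list of n x m numeric matrices with standardised
#'   columns (a single matrix is wrapped), or a `"genotypes"` /
#'   `"methylation"` object (standardised internally).
#' @param phenotype a [residualize()] result or numeric vector (it is used
#'   as given; pass a standardised phenotype).
#' @param covariates data frame of fixed-effect covariates (factors
#'   expanded; an intercept is always added), or `NULL` for intercept only.
#' @param priors a [mixture_prior()] applied to every group, or a list of
#'   one prior per group.
#' @param chain a [chain_config()].
#' @param intercept set `FALSE` (with `covariates = NULL`) to fit with no
#'   fixed effects at all, e.g. for pre-centred toy problems.
#' @param fix list of hyperparameters to hold fixed instead of sampling:
#'   `sigma_g` (numeric, one per group), `sigma_e` (single value), `pi`
#'   (list of probability vectors, spike first). Mainly for validation
#'   against enumeration oracles.
#' @param nu0,s02 degrees of freedom and scale of the weakly informative
#'   scaled inverse-chi-square priors on sigma_g^2 and sigma_e^2.
#' @return object of class `"bayesmix"`; see [summary.bayesmix()],
#'   [variance_partition()], [significant_markers()].
#' @export
bayesmix <- function(groups, phenotype, covariates = NULL,
                     priors = mixture_prior(), chain = chain_config(),
                     intercept = TRUE, fix = list(), nu0 = 0.001, s02 = 0.001) {
  if (inherits(groups, "genotypes"))
    groups <- list(snp = standardize_columns(groups$dosages))
  if (inherits(groups, "methylation"))
    groups <- list(cpg = standardize_columns(groups$values))
  if (is.matrix(groups)) groups <- list(g1 = groups)
  if (!is.list(groups) || !length(groups)) stop_arg("`groups` must be a list of matrices")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  G <- length(groups)
  groups <- lapply(groups, as.matrix)
  for (g in seq_len(G)) check_standardized(groups[[g]], names(groups)[g])

  y <- pheno_vector(phenotype)
  n <- length(y)
  if (any(vapply(groups, nrow, 0L) != n))
    stop_arg("group row counts differ from the phenotype length")

  if (inherits(priors, "mixture_prior")) priors <- rep(list(priors), G)
  if (length(priors) != G) stop_arg("need one prior per group")
  if (!all(vapply(priors, inherits, TRUE, "mixture_prior")))
    stop_arg("`priors` must be mixture_prior objects")
  if (!inherits(chain, "chain_config")) stop_arg("`chain` must be a chain_config()")

  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    C <- if (intercept) matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
         else matrix(0, n, 0L)
  } else {
    C <- model.matrix(~ ., data = as.data.frame(covariates))
    if (!intercept) C <- C[, colnames(C) != "(Intercept)", drop = FALSE]
  }

  fix_sigma_g <- rep(NA_real_, G)
  if (!is.null(fix$sigma_g)) fix_sigma_g <- rep_len(as.numeric(fix$sigma_g), G)
  fix_sigma_e <- if (is.null(fix$sigma_e)) NA_real_ else as.numeric(fix$sigma_e)
  fix_pi <- fix$pi %||% vector("list", G)
  if (!is.list(fix_pi)) fix_pi <- rep(list(fix_pi), G)

  set.seed(chain$seed)
  res <- gibbs_mixture(
    y = as.numeric(y), C = C, Xg = unname(groups),
    comp_var = lapply(priors, `[[`, "component_variances"),
    dirichlet = lapply(priors, `[[`, "dirichlet"),
    relative_scale = vapply(priors, function(p) p$scale == "relative", TRUE),
    n_iter = chain$n_iter, burn_in = chain$burn_in, thin = chain$thin,
    fix_sigma_g = fix_sigma_g, fix_sigma_e = fix_sigma_e, fix_pi = fix_pi,
    nu0 = nu0, s02 = s02)
  if (res$n_retained < 100)
    warning("only ", res$n_retained, " retained draws; posterior summaries are noisy")

  marker <- do.call(rbind, lapply(seq_len(G), function(g) {
    ids <- colnames(groups[[g]]) %||% sprintf("m%05d", seq_len(ncol(groups[[g]])))
    data.frame(group = names(groups)[g], id = ids,
               pip = res$marker[[g]]$pip,
               beta_mean = res$marker[[g]]$beta_mean,
               beta_sd = res$marker[[g]]$beta_sd,
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  colnames(res$share_draws) <- names(groups)
  cs_names <- unlist(lapply(seq_len(G), function(g)
    paste0(names(groups)[g], ".c", seq_along(priors[[g]]$component_variances))))
  colnames(res$comp_share_draws) <- cs_names
  colnames(res$sigma_g_draws) <- names(groups)
  pi_names <- unlist(lapply(seq_len(G), function(g)
    paste0(names(groups)[g], ".pi", 0:length(priors[[g]]$component_variances))))
  colnames(res$pi_draws) <- pi_names

  structure(list(
    marker = marker,
    draws = list(share = res$share_draws, comp_share = res$comp_share_draws,
                 sigma_g = res$sigma_g_draws, sigma_e = as.numeric(res$sigma_e_draws),
                 pi = res$pi_draws),
    fitted = setNames(as.numeric(res$fitted), names(y)),
    y = y, groups = names(groups), priors = priors, chain = chain,
    n = n, n_markers = vapply(groups, ncol, 0L),
    n_retained = res$n_retained, var_y = res$var_y),
    class = "bayesmix")
}

#' @export
print.bayesmix <- function(x, ...) {
  cat("Grouped spike-and-slab mixture fit\n")
  cat("  n =", x$n, "; groups:",
      paste(sprintf("%s (%d markers)", x$groups, x$n_markers), collapse = ", "), "\n")
  cat("  retained draws:", x$n_retained,
      sprintf("(%d iterations, %d burn-in, thin %d, seed %d)\n",
              x$chain$n_iter, x$chain$burn_in, x$chain$thin, x$chain$seed))
  vp <- variance_partition(x)
  cat("  posterior variance shares:\n")
  for (i in seq_len(nrow(vp)))
    cat(sprintf("    %s: %.3f [%.3f, %.3f]\n", vp$group[i], vp$mean_share[i],
                vp$ci_lower[i], vp$ci_upper[i]))
  invisible(x)
}

#' Summarise a mixture fit
#'
#' @param object a [bayesmix()] fit.
#' @param pip_threshold PIP cut-off used for the significant-marker table.
#' @param ... unused.
#' @return list of class `"summary.bayesmix"` with the variance partition,
#'   significant markers and chain details.
#' @export
summary.bayesmix <- function(object, pip_threshold = object$chain$pip_threshold, ...) {
  structure(list(partition = variance_partition(object),
                 significant = significant_markers(object, pip_threshold),
                 pip_threshold = pip_threshold,
                 n = object$n, n_retained = object$n_retained,
                 groups = object$groups, n_markers = object$n_markers),
            class = "summary.bayesmix")
}

#' @export
print.summary.bayesmix <- function(x, ...) {
  cat("Variance partition (posterior mean share and 95% credible interval):\n")
  print(x$partition, row.names = FALSE)
  cat("\nMarkers with PIP >=", x$pip_threshold, ":", nrow(x$significant), "\n")
  if (nrow(x$significant)) print(head(x$significant, 20L), row.names = FALSE)
  invisible(x)
}

#' @export
coef.bayesmix <- function(object, ...) {
  setNames(object$marker$beta_mean, object$marker$id)
}

#' @export
fitted.bayesmix <- function(object, ...) object$fitted

#' @export
residuals.bayesmix <- function(object, ...) object$y - object$fitted

#' Trace and posterior plots for a mixture fit
#'
#' Draws the variance-share trace per group and the posterior density of
#' each group's share (base graphics).
#'
#' @param x a [bayesmix()] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.bayesmix <- function(x, ...) {
  sh <- x$draws$share
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(sh, type = "l", lty = 1, xlab = "retained draw",
                    ylab = "variance share", main = "Share trace", ...)
  graphics::legend("topright", legend = colnames(sh), col = seq_len(ncol(sh)),
                   lty = 1, bty = "n")
  dens <- lapply(seq_len(ncol(sh)), function(j) stats::density(sh[, j]))
  xl <- range(unlist(lapply(dens, `[[`, "x")))
  yl <- range(unlist(lapply(dens, `[[`, "y")))
  graphics::plot(NA, xlim = xl, ylim = yl, xlab = "variance share",
                 ylab = "density", main = "Posterior share")
  for (j in seq_along(dens)) graphics::lines(dens[[j]], col = j)
  invisible(x)
}

#' Markers passing the posterior-inclusion-probability threshold
#'
#' @param posterior a [bayesmix()] fit.
#' @param pip_threshold inclusion cut-off; markers with
#'   `pip >= pip_threshold` are reported (>= semantics, so a PIP of exactly
#'   0.95 passes the default).
#' @return marker summary rows sorted by descending PIP.
#' @export
significant_markers <- function(posterior, pip_threshold = 0.95) {
  if (!inherits(posterior, "bayesmix")) stop_arg("`posterior` must be a bayesmix fit")
  check_number(pip_threshold, "pip_threshold", 0, 1)
  m <- posterior$marker[posterior$marker$pip >= pip_threshold, , drop = FALSE]
  m[order(-m$pip), , drop = FALSE]
}

#' Posterior variance partition across marker groups
#'
#' Per group: posterior mean variance share, 95% credible interval
#' (2.5th/97.5th percentiles of the retained draws) and the share
#' attributable to each mixture component. Component attributions are
#' covariance decompositions, so within every draw they sum exactly to the
#' group's total share.
#'
#' @param posterior a [bayesmix()] fit with at least 100 retained draws.
#' @param level credible-interval level.
#' @return data frame with one row per group: `group`, `mean_share`,
#'   `ci_lower`, `ci_upper`, then one `share_c<k>` column per component.
#' @export
variance_partition <- function(posterior, level = 0.95) {
  if (!inherits(posterior, "bayesmix")) stop_arg("`posterior` must be a bayesmix fit")
  if (posterior$n_retained < 100)
    stop_arg("need at least 100 retained draws for a stable partition")
  a <- (1 - level) / 2
  sh <- posterior$draws$share
  cs <- posterior$draws$comp_share
  out <- data.frame(group = colnames(sh),
                    mean_share = colMeans(sh),
                    ci_lower = apply(sh, 2L, quantile, probs = a),
                    ci_upper = apply(sh, 2L, quantile, probs = 1 - a),
                    stringsAsFactors = FALSE, row.names = NULL)
  kmax <- max(vapply(posterior$priors, function(p) length(p$component_variances), 0L))
  for (k in seq_len(kmax)) out[[paste0("share_c", k)]] <- NA_real_
  for (g in seq_along(posterior$groups)) {
    nm <- posterior$groups[g]
    kk <- length(posterior$priors[[g]]$component_variances)
    for (k in seq_len(kk))
      out[g, paste0("share_c", k)] <- mean(cs[, paste0(nm, ".c", k)])
  }
  out
}

#' Compare two variance-share posteriors
#'
#' Welch two-sample t-test between the variance-share draws of a
#' stand-alone fit and those of a combined (conditional) fit, asking
#' whether conditioning on the other omics group changed the estimate.
#'
#' @param draws_alone,draws_conditional numeric vectors of at least 30
#'   retained share draws each.
#' @return list with `t`, `p`, and the two means.
#' @export
compare_variance_posteriors <- function(draws_alone, draws_conditional) {
  if (length(draws_alone) < 30L || length(draws_conditional) < 30L)
    stop_arg("need at least 30 draws per posterior")
  va <- var(draws_alone); vc <- var(draws_conditional)
  if (va == 0 && vc == 0) {
    eq <- isTRUE(all.equal(mean(draws_alone), mean(draws_conditional)))
    return(list(t = if (eq) 0 else Inf, p = if (eq) 1 else 0,
                mean_alone = mean(draws_alone),
                mean_conditional = mean(draws_conditional)))
  }
  ht <- t.test(draws_alone, draws_conditional)
  list(t = unname(ht$statistic), p = ht$p.value,
       mean_alone = mean(draws_alone), mean_conditional = mean(draws_conditional))
}
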