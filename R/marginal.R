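#' Bonferroni-corrected significance threshold across phenotypes
#'
#' Divides a genome-wide significance level by the number of phenotypes
#' scanned, e.g. 5.0e-8 / 70 = 7.14e-10 for SNPs and 3.6e-8 / 70 = 5.14e-10
#' for CpG probes.
#'
#' @param genomewide_alpha genome-wide significance level in (0, 1).
#' @param n_phenotypes number of phenotypes tested.
#' @return `genomewide_alpha / n_phenotypes`.
#' @export
bonferroni_threshold <- function(genomewide_alpha, n_phenotypes) {
  check_number(genomewide_alpha, "genomewide_alpha", 0, 1,
               strict_lower = TRUE, strict_upper = TRUE)
  n_phenotypes <- check_count(n_phenotypes, "n_phenotypes")
  genomewide_alpha / n_phenotypes
}

## coerce marker input to (matrix, map) with canonical columns
marker_block <- function(markers) {
  if (inherits(markers, "genotypes")) {
    map <- markers$snp_map
    list(x = markers$dosages, standardize = FALSE,
         map = data.frame(id = map$snp_id, chrom = map$chrom, pos = map$pos,
                          effect_allele = map$effect_allele,
                          other_allele = map$other_allele,
                          eaf = colMeans(markers$dosages) / 2,
                          stringsAsFactors = FALSE))
  } else if (inherits(markers, "methylation")) {
    map <- markers$cpg_map
    list(x = markers$values, standardize = TRUE,
         map = data.frame(id = map$probe_id, chrom = map$chrom, pos = map$pos,
                          effect_allele = NA_character_,
                          other_allele = NA_character_, eaf = NA_real_,
                          stringsAsFactors = FALSE))
  } else if (is.matrix(markers)) {
    ids <- colnames(markers) %||% sprintf("m%05d", seq_len(ncol(markers)))
    list(x = markers, standardize = FALSE,
         map = data.frame(id = ids, chrom = "1", pos = seq_len(ncol(markers)),
                          effect_allele = NA_character_,
                          other_allele = NA_character_, eaf = NA_real_,
                          stringsAsFactors = FALSE))
  } else stop_arg("`markers` must be a genotypes, methylation or matrix object")
}

#' Marginal ordinary-least-squares association scan
#'
#' Regresses the phenotype on each marker in turn (plus optional covariates),
#' returning per-marker effect size, standard error and a two-sided p-value
#' from the t distribution. Genotype dosages enter on the allele-count scale
#' (beta is per effect allele); methylation probes are standardised first
#' (beta is per SD of methylation). Monomorphic markers are skipped and
#' recorded in `attr(, "skipped")`.
#'
#' @param markers a `"genotypes"` or `"methylation"` object, or a plain
#'   n x m matrix.
#' @param phenotype a [residualize()] result or numeric vector, aligned with
#'   the marker rows.
#' @param covariates optional covariate data frame (factors expanded).
#' @return summary-statistics data frame (one row per tested marker) with
#'   columns id, chrom, pos, effect_allele, other_allele, eaf, beta, se, p, n.
#' @export
ols_scan <- function(markers, phenotype, covariates = NULL) {
  blk <- marker_block(markers)
  y <- pheno_vector(phenotype)
  X <- blk$x
  if (nrow(X) != length(y)) stop_arg("marker rows and phenotype length differ")
  n <- length(y)

  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    C <- matrix(1, n, 1L)
  } else {
    C <- model.matrix(~ ., data = as.data.frame(covariates))
  }
  if (n <= ncol(C) + 2L) stop_arg("too few samples for the covariate count")

  keep <- apply(X, 2L, var) > 0
  if (any(!keep))
    message(sum(!keep), " monomorphic marker(s) skipped")
  Xk <- X[, keep, drop = FALSE]
  if (blk$standardize) Xk <- standardize_columns(Xk)

  qc <- qr(C)
  yr <- qr.resid(qc, y)
  Xr <- qr.resid(qc, Xk)
  df <- n - ncol(C) - 1L

  xtx <- colSums(Xr^2)
  xty <- drop(crossprod(Xr, yr))
  beta <- xty / xtx
  yty <- sum(yr^2)
  rss <- pmax(yty - beta * xty, 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / xtx)
  tstat <- beta / se
  p <- clamp_p(2 * pt(-abs(tstat), df))
  ## perfect fits drive se to 0; keep the record with the underflow-guarded p
  p[se == 0] <- 1e-320

  out <- new_sumstats(blk$map$id[keep], blk$map$chrom[keep], blk$map$pos[keep],
                      blk$map$effect_allele[keep], blk$map$other_allele[keep],
                      blk$map$eaf[keep], beta, se, p, n)
  attr(out, "skipped") <- blk$map$id[!keep]
  out
}

#' Stepwise conditional association analysis
#'
#' Forward selection on a fixed significance threshold: repeatedly scans the
#' phenotype residualised on the currently selected markers, adds the
#' most significant marker while its p-value is below `threshold`, and
#' reports the selected markers with effect sizes from the final joint
#' model. Ties on p are broken by lowest (chrom, pos).
#'
#' @param genotypes a `"genotypes"` object.
#' @param phenotype prepared phenotype or numeric vector.
#' @param threshold conditional significance threshold in (0, 1), e.g.
#'   [bonferroni_threshold()] output.
#' @param covariates optional covariate data frame, carried through every
#'   conditional scan.
#' @return data frame of conditionally significant markers (id, chrom, pos,
#'   beta, se, p from the joint model, and `p_entry`, the conditional
#'   p-value at inclusion); zero rows when nothing passes.
#' @export
stepwise_conditional <- function(genotypes, phenotype, threshold,
                                 covariates = NULL) {
  check_number(threshold, "threshold", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  y <- pheno_vector(phenotype)
  X <- genotypes$dosages
  map <- genotypes$snp_map
  n <- length(y)
  selected <- character(0)
  p_entry <- numeric(0)

  repeat {
    if (length(selected) >= n / 2)
      stop_arg("selected ", length(selected), " markers (half the sample size); ",
               "aborting: pathological collinearity or threshold too lax")
    remaining <- setdiff(colnames(X), selected)
    if (!length(remaining)) break
    covs <- as.data.frame(covariates %||% data.frame(row.names = seq_len(n)))
    if (length(selected))
      covs <- cbind(covs, as.data.frame(X[, selected, drop = FALSE]))
    scan <- ols_scan(structure(list(dosages = X[, remaining, drop = FALSE],
                                    snp_map = map[map$snp_id %in% remaining, ,
                                                  drop = FALSE]),
                               class = "genotypes"),
                     y, covariates = if (ncol(covs)) covs else NULL)
    if (!nrow(scan)) break
    best <- scan[order(scan$p, scan$chrom, scan$pos), ][1L, ]
    if (best$p >= threshold) break
    selected <- c(selected, best$id)
    p_entry <- c(p_entry, best$p)
  }

  if (!length(selected)) {
    out <- new_sumstats(character(0), character(0), integer(0), character(0),
                        character(0), numeric(0), numeric(0), numeric(0),
                        numeric(0), integer(0))
    out$p_entry <- numeric(0)
    return(out)
  }

  ## joint refit of all selected markers
  dat <- data.frame(y = y, X[, selected, drop = FALSE], check.names = FALSE)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  fit <- lm(y ~ ., data = dat)
  cf <- summary(fit)$coefficients
  rows <- match(selected, map$snp_id)
  jm <- cf[match(selected, rownames(cf)), , drop = FALSE]
  ## lm backtick-quotes non-syntactic names
  if (anyNA(jm[, 1L]))
    jm <- cf[match(paste0("`", selected, "`"), rownames(cf)), , drop = FALSE]
  out <- new_sumstats(selected, map$chrom[rows], map$pos[rows],
                      map$effect_allele[rows], map$other_allele[rows],
                      colMeans(X[, selected, drop = FALSE]) / 2,
                      jm[, 1L], jm[, 2L], clamp_p(jm[, 4L]), n)
  out$p_entry <- p_entry
  out
}

## EMMA-style restricted log-likelihood in the rotated basis, profiled over
## the total variance; lambda and delta on sigma_e^2 / sigma_g^2 scale
reml_loglik <- function(log_delta, ev, ystar, Cstar) {
  delta <- exp(log_delta)
  w <- ev + delta
  n <- length(ystar)
  p <- ncol(Cstar)
  W <- Cstar / w
  XtWX <- crossprod(Cstar, W)
  b <- solve(XtWX, crossprod(W, ystar))
  r <- ystar - Cstar %*% b
  rss <- sum(r^2 / w)
  -0.5 * ((n - p) * log(rss) + sum(log(w)) + determinant(XtWX)$modulus[1])
}

#' Mixed-model epigenome-wide association scan
#'
#' Tests each probe against the phenotype while fitting a methylation
#' relatedness matrix `K = M M' / m` (from all standardised probes,
#' including the candidate) as a random effect. The variance components are
#' estimated once by REML on the null model via a single eigendecomposition
#' of `K`, then every probe is tested by generalised least squares in the
#' rotated basis — the strategy of mixed-model omic-association software.
#'
#' @param methylation a `"methylation"` object (>= 2 probes).
#' @param phenotype prepared phenotype or numeric vector.
#' @param covariates optional covariate data frame.
#' @param delta optional fixed ratio sigma_e^2 / sigma_g^2; `NULL` (default)
#'   estimates it by REML. `Inf` forces the random-effect variance to zero,
#'   reducing the scan to [ols_scan()].
#' @return summary-statistics data frame, one row per probe (beta per SD of
#'   methylation).
#' @export
mlm_ewas <- function(methylation, phenotype, covariates = NULL, delta = NULL) {
  if (!inherits(methylation, "methylation"))
    stop_arg("`methylation` must be a methylation object")
  M <- methylation$values
  if (ncol(M) < 2L) stop_arg("need at least 2 probes to form a relatedness matrix")
  y <- pheno_vector(phenotype)
  n <- length(y)
  if (nrow(M) != n) stop_arg("methylation rows and phenotype length differ")

  Ms <- standardize_columns(M)
  K <- tcrossprod(Ms) / ncol(Ms)
  eig <- eigen(K, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  if (all(ev <= 1e-12)) stop_arg("relatedness matrix is numerically zero")
  U <- eig$vectors

  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    C <- matrix(1, n, 1L)
  } else {
    C <- model.matrix(~ ., data = as.data.frame(covariates))
  }
  ystar <- drop(crossprod(U, y))
  Cstar <- crossprod(U, C)

  if (is.null(delta)) {
    opt <- optimize(reml_loglik, interval = c(-10, 10), maximum = TRUE,
                    ev = ev, ystar = ystar, Cstar = Cstar)
    delta <- exp(opt$maximum)
  } else if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0) {
    stop_arg("`delta` must be a single non-negative number (Inf allowed)")
  }
  w <- if (is.infinite(delta)) rep(1, n) else ev + delta
  sw <- 1 / sqrt(w)

  ## GLS for every probe in the rotated, whitened basis
  yw <- ystar * sw
  Cw <- Cstar * sw
  Xw <- crossprod(U, Ms) * sw
  qc <- qr(Cw)
  yr <- qr.resid(qc, yw)
  Xr <- qr.resid(qc, Xw)
  df <- n - ncol(Cw) - 1L
  xtx <- colSums(Xr^2)
  beta <- drop(crossprod(Xr, yr)) / xtx
  rss <- pmax(sum(yr^2) - beta^2 * xtx, 0)
  se <- sqrt(rss / df / xtx)
  p <- clamp_p(2 * pt(-abs(beta / se), df))

  map <- methylation$cpg_map
  out <- new_sumstats(map$probe_id, map$chrom, map$pos, NA_character_,
                      NA_character_, NA_real_, beta, se, p, n)
  attr(out, "delta") <- delta
  out
}

#' Genomic inflation factor
#'
#' Lambda is the median of the chi-squared(1) statistics implied by the
#' p-values divided by the null median 0.4549364. Lambda near 1 indicates a
#' calibrated scan; lambda > 1, inflation from confounding or polygenicity.
#'
#' @param pvalues vector of p-values in (0, 1].
#' @return single numeric lambda.
#' @export
genomic_inflation <- function(pvalues) {
  if (!length(pvalues)) stop_arg("empty p-value vector")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop_arg("p-values must lie in (0, 1]")
  chisq <- qchisq(pvalues, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}

#' Percent attenuation of an effect size after covariate adjustment
#'
#' `100 * (|beta_unadjusted| - |beta_adjusted|) / |beta_unadjusted|`; e.g.
#' a smoking-sensitive probe effect moving from -1.74 to -1.20 on smoking
#' adjustment is attenuated by 31.03%. If adjustment flips the sign of the
#' effect the percentage is not meaningful: `NA` is returned with
#' `attr(, "sign_flip") = TRUE` and a warning.
#'
#' @param beta_unadjusted effect before adjustment (non-zero).
#' @param beta_adjusted effect after adjustment.
#' @return percent attenuation (may be negative if the effect grew).
#' @export
attenuation_percent <- function(beta_unadjusted, beta_adjusted) {
  check_number(beta_unadjusted, "beta_unadjusted")
  check_number(beta_adjusted, "beta_adjusted")
  if (beta_unadjusted == 0) stop_arg("`beta_unadjusted` must be non-zero")
  if (beta_adjusted != 0 && sign(beta_adjusted) != sign(beta_unadjusted)) {
    warning("adjusted effect changed sign; attenuation percentage undefined")
    return(structure(NA_real_, sign_flip = TRUE))
  }
  100 * (abs(beta_unadjusted) - abs(beta_adjusted)) / abs(beta_unadjusted)
}
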