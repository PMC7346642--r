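#' @useDynLib protarch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef complete.cases cor cov lm lm.fit median model.matrix
#'   optimize p.adjust pchisq phyper pnorm pt qchisq qnorm quantile rbinom
#'   rgamma rnorm runif sd setNames t.test var
#' @importFrom utils read.table write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_arg("`", name, "` must be a single finite number")
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_arg("`", name, "` = ", x, " is outside its valid range")
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_arg("`", name, "` must be an integer >= ", min)
  as.integer(x)
}

#' Column-standardise a matrix
#'
#' Centres each column to mean zero and scales to unit (sample) variance, as
#' required for marker blocks entering [bayesmix()]. Zero-variance columns
#' raise an error rather than silently producing `NaN`.
#'
#' @param x numeric matrix (individuals in rows, markers in columns).
#' @return matrix of the same shape with standardised columns.
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2L, sd)
  if (any(sds == 0 | !is.finite(sds)))
    stop_arg("cannot standardise zero-variance column(s): ",
             paste(colnames(x)[sds == 0 | !is.finite(sds)], collapse = ", "))
  out <- scale(x)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

## Canonical per-marker association record shared by scans, coloc and MR.
sumstats_cols <- c("id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "p", "n")

new_sumstats <- function(id, chrom, pos, effect_allele, other_allele,
                         eaf, beta, se, p, n) {
  data.frame(id = as.character(id), chrom = as.character(chrom),
             pos = as.integer(pos),
             effect_allele = as.character(effect_allele),
             other_allele = as.character(other_allele),
             eaf = as.numeric(eaf), beta = as.numeric(beta),
             se = as.numeric(se), p = as.numeric(p), n = as.integer(n),
             stringsAsFactors = FALSE, row.names = NULL)
}

check_sumstats <- function(stats, name = "stats") {
  if (!is.data.frame(stats) || !all(sumstats_cols %in% names(stats)))
    stop_arg("`", name, "` must be a summary-statistics data frame with columns ",
             paste(sumstats_cols, collapse = ", "))
  if (any(stats$se <= 0, na.rm = TRUE))
    stop_arg("`", name, "` contains non-positive standard errors")
  invisible(stats)
}

## p-value floor: two-sided normal/t tails underflow below ~1e-320
clamp_p <- function(p) pmax(p, 1e-320)

logsumexp <- function(l) {
  m <- max(l)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(l - m)))
}
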