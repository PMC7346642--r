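#' Construct a protein panel
#'
#' Container for a multiplex protein-abundance panel with per-measurement
#' limit-of-detection flags and the genomic coordinates of each protein's
#' encoding gene (used downstream for cis/trans classification).
#'
#' @param values numeric matrix, proteins in rows, individuals in columns;
#'   dimnames required.
#' @param lod_flags logical matrix of the same shape, `TRUE` where the
#'   measurement fell below the assay's lowest limit of detection.
#' @param protein_map data frame with columns `protein`, `chrom`, `tss`
#'   (1-based transcription start site of the encoding gene); optional.
#' @return object of class `"protein_panel"`.
#' @export
protein_panel <- function(values, lod_flags = NULL, protein_map = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_arg("`values` needs protein rownames and sample colnames")
  if (anyDuplicated(colnames(values))) stop_arg("sample ids must be unique")
  if (is.null(lod_flags)) {
    lod_flags <- matrix(FALSE, nrow(values), ncol(values), dimnames = dimnames(values))
  }
  lod_flags <- as.matrix(lod_flags)
  if (!identical(dim(lod_flags), dim(values)))
    stop_arg("`lod_flags` must have the same shape as `values`")
  structure(list(values = values, lod_flags = lod_flags,
                 protein_map = protein_map), class = "protein_panel")
}

#' @export
print.protein_panel <- function(x, ...) {
  cat("Protein panel:", nrow(x$values), "proteins x", ncol(x$values), "samples;",
      sum(x$lod_flags), "measurements below LOD\n")
  invisible(x)
}

#' Remove proteins with too many values below the limit of detection
#'
#' A protein is removed when strictly more than `max_below_frac` of its
#' samples fall below the assay's lowest limit of detection ("over 40%" is
#' read as a strict inequality: exactly 40% is retained).
#'
#' @param panel a [protein_panel()].
#' @param max_below_frac removal threshold on the below-LOD fraction
#'   (default 0.40).
#' @return the filtered panel; removed proteins and their below-LOD
#'   fractions are recorded in `attr(, "removed")`.
#' @export
lod_filter <- function(panel, max_below_frac = 0.40) {
  if (!inherits(panel, "protein_panel")) stop_arg("`panel` must be a protein_panel")
  check_number(max_below_frac, "max_below_frac", 0, 1)
  frac <- rowMeans(panel$lod_flags)
  drop <- frac > max_below_frac
  removed <- data.frame(protein = rownames(panel$values)[drop],
                        below_lod_frac = frac[drop], row.names = NULL)
  if (all(drop)) warning("all proteins removed by LOD filter")
  kept <- rownames(panel$values)[!drop]
  map <- panel$protein_map
  if (!is.null(map)) map <- map[map$protein %in% kept, , drop = FALSE]
  out <- protein_panel(panel$values[!drop, , drop = FALSE],
                       panel$lod_flags[!drop, , drop = FALSE], map)
  attr(out, "removed") <- removed
  out
}

#' Rank-based inverse normal transformation
#'
#' Maps values through the standard normal quantile function at
#' `(rank - 0.5) / n` (or the Blom offset `(rank - 3/8) / (n + 1/4)`),
#' with ties receiving their average rank. Missing values propagate and do
#' not contribute to `n`. The result depends on the input only through its
#' ranks, so any strictly monotone transform of the input yields an
#' identical output.
#'
#' @param x numeric vector with at least 3 non-missing, non-constant values.
#' @param offset rank-offset convention, `"half"` (default) or `"blom"`.
#' @return numeric vector of normal scores, same length as `x`.
#' @export
rank_inverse_normal <- function(x, offset = c("half", "blom")) {
  offset <- match.arg(offset)
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3L) stop_arg("need at least 3 non-missing values")
  if (length(unique(x[ok])) == 1L)
    stop_arg("all non-missing values are identical; ranks are undefined")
  r <- rank(x, na.last = "keep")  # average ranks on ties
  q <- switch(offset,
              half = (r - 0.5) / n,
              blom = (r - 3 / 8) / (n + 1 / 4))
  qnorm(q)
}

#' Residualise a phenotype on covariates and standardise
#'
#' Fits ordinary least squares of the phenotype on the covariates (factors
#' expanded to indicator contrasts, intercept always included), then scales
#' the residuals to mean 0 and variance 1. Samples with a missing phenotype
#' are dropped and recorded; missing covariates among retained samples are
#' an error, as is a rank-deficient design or a perfect fit (zero residual
#' variance).
#'
#' @param values named numeric phenotype vector.
#' @param covariates data frame of covariates in the same sample order, or
#'   `NULL` for intercept-only (plain z-scoring).
#' @return object of class `"prepared_phenotype"`: list with `residuals`
#'   (standardised, named), `covariates_used`, `n`, and `dropped` (ids of
#'   samples removed for missing phenotype).
#' @export
residualize <- function(values, covariates = NULL) {
  if (!is.numeric(values)) stop_arg("`values` must be numeric")
  ids <- names(values) %||% as.character(seq_along(values))
  keep <- !is.na(values)
  dropped <- ids[!keep]
  y <- values[keep]
  if (length(y) < 3L) stop_arg("fewer than 3 non-missing phenotype values")

  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    X <- matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
    used <- character(0)
  } else {
    covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
    if (anyNA(covariates)) stop_arg("missing covariate values for retained samples")
    X <- model.matrix(~ ., data = covariates)
    used <- names(covariates)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop_arg("covariate matrix is rank deficient; collinear column(s): ",
             paste(bad, collapse = ", "))
  }
  res <- qr.resid(qx, y)
  if (var(res) < 1e-12 * max(var(y), 1))
    stop_arg("zero residual variance: covariates fit the phenotype perfectly")
  res <- (res - mean(res)) / sd(res)
  names(res) <- ids[keep]
  structure(list(residuals = res, covariates_used = used,
                 n = length(res), dropped = dropped),
            class = "prepared_phenotype")
}

#' @export
print.prepared_phenotype <- function(x, ...) {
  cat("Prepared phenotype: n =", x$n, "\n")
  if (length(x$covariates_used))
    cat("Residualised on:", paste(x$covariates_used, collapse = ", "), "\n")
  if (length(x$dropped)) cat("Dropped (missing phenotype):", length(x$dropped), "\n")
  invisible(x)
}

## accept a prepared_phenotype or a bare numeric vector
pheno_vector <- function(phenotype) {
  if (inherits(phenotype, "prepared_phenotype")) phenotype$residuals
  else if (is.numeric(phenotype)) phenotype
  else stop_arg("`phenotype` must be numeric or a prepared_phenotype")
}
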