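#' Linkage-disequilibrium r-squared between two dosage vectors
#'
#' Squared Pearson correlation of genotype dosages; invariant to flipping
#' the coded allele of either variant.
#'
#' @param g1,g2 numeric dosage vectors of equal length (>= 3), both
#'   polymorphic.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(g1, g2) {
  if (length(g1) != length(g2) || length(g1) < 3L)
    stop_arg("dosage vectors must have equal length >= 3")
  if (var(g1) == 0 || var(g2) == 0)
    stop_arg("monomorphic variant: LD undefined")
  cor(g1, g2)^2
}

#' Classify a variant as cis or trans relative to a gene
#'
#' A variant is cis when it lies on the same chromosome within `window_bp`
#' of the gene's transcription start site (10 Mb by default); the boundary
#' is inclusive. Vectorised over variants.
#'
#' @param snp_chrom,snp_pos variant chromosome and 1-based position.
#' @param gene_chrom,gene_tss chromosome and 1-based TSS of the encoding
#'   gene.
#' @param window_bp cis window in base pairs.
#' @return character vector of `"cis"` / `"trans"`.
#' @export
classify_cis_trans <- function(snp_chrom, snp_pos, gene_chrom, gene_tss,
                               window_bp = 10000000) {
  check_number(window_bp, "window_bp", 0, Inf)
  ifelse(as.character(snp_chrom) == as.character(gene_chrom) &
           abs(as.numeric(snp_pos) - as.numeric(gene_tss)) <= window_bp,
         "cis", "trans")
}

#' Construct a per-method hit set
#'
#' @param method `"OLS"`, `"mixed"` or `"bayes"`.
#' @param protein protein name the hits refer to.
#' @param markers data frame with columns `id`, `chrom`, `pos`, `beta` and
#'   `criterion` (p-value for OLS/mixed, PIP for bayes).
#' @return object of class `"hit_set"`.
#' @export
hit_set <- function(method = c("OLS", "mixed", "bayes"), protein, markers) {
  method <- match.arg(method)
  need <- c("id", "chrom", "pos", "beta", "criterion")
  if (!is.data.frame(markers) || !all(need %in% names(markers)))
    stop_arg("`markers` needs columns ", paste(need, collapse = ", "))
  structure(list(method = method, protein = protein,
                 markers = markers[, need, drop = FALSE]), class = "hit_set")
}

#' Cross-method concordance of association hits
#'
#' A marker is concordant when every hit set contains it directly or
#' contains a variant in high LD with it (`r2 > ld_threshold`, strict). LD
#' is computed on the analysis sample's dosages. For each concordant marker
#' the linking variant and its r-squared are reported per method.
#'
#' @param hitsets list of [hit_set()] objects for the same protein
#'   (at least 2).
#' @param genotypes a `"genotypes"` object containing every hit marker.
#' @param ld_threshold LD r-squared above which two variants count as
#'   proxies (default 0.75).
#' @return data frame: protein, marker, one `<method>_via` and
#'   `<method>_r2` column pair per method, and `concordant` flag;
#'   `attr(, "concordant")` lists the concordant marker ids.
#' @export
triangulate <- function(hitsets, genotypes, ld_threshold = 0.75) {
  if (length(hitsets) < 2L) stop_arg("need at least 2 hit sets")
  if (!all(vapply(hitsets, inherits, TRUE, "hit_set")))
    stop_arg("`hitsets` must be hit_set objects")
  check_number(ld_threshold, "ld_threshold", 0, 1)
  dos <- genotypes$dosages
  all_ids <- unique(unlist(lapply(hitsets, function(h) h$markers$id)))
  missing <- setdiff(all_ids, colnames(dos))
  if (length(missing))
    stop_arg("marker(s) absent from genotype matrix: ",
             paste(missing, collapse = ", "))

  methods <- vapply(hitsets, `[[`, "", "method")
  protein <- hitsets[[1L]]$protein
  rows <- lapply(all_ids, function(id) {
    row <- list(protein = protein, marker = id)
    ok <- TRUE
    for (h in seq_along(hitsets)) {
      ids_h <- hitsets[[h]]$markers$id
      if (id %in% ids_h) {
        via <- id; r2 <- 1.0
      } else {
        r2s <- vapply(ids_h, function(o) ld_r2(dos[, id], dos[, o]), 0.0)
        best <- which.max(r2s)
        if (length(best) && r2s[best] > ld_threshold) {
          via <- ids_h[best]; r2 <- r2s[best]
        } else {
          via <- NA_character_; r2 <- if (length(best)) r2s[best] else NA_real_
          ok <- FALSE
        }
      }
      row[[paste0(methods[h], "_via")]] <- via
      row[[paste0(methods[h], "_r2")]] <- r2
    }
    row$concordant <- ok
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "concordant") <- out$marker[out$concordant]
  out
}

#' Correlation between two sets of effect sizes
#'
#' Pearson correlation of matched effect estimates with a Fisher-z 95%
#' confidence interval. With allele information supplied, effects reported
#' on the opposite allele are sign-flipped before correlating.
#'
#' @param betas_a,betas_b matched numeric effect vectors (length >= 3).
#' @param effect_a,effect_b optional effect-allele vectors used for
#'   alignment.
#' @param align_alleles flip `betas_b` where the effect alleles differ.
#' @param level confidence level for the interval.
#' @return list with `r`, `ci` (length 2), `n`, and `n_flipped`.
#' @export
effect_correlation <- function(betas_a, betas_b, effect_a = NULL,
                               effect_b = NULL, align_alleles = TRUE,
                               level = 0.95) {
  if (length(betas_a) != length(betas_b))
    stop_arg("effect vectors must be matched")
  n_flipped <- 0L
  if (align_alleles && !is.null(effect_a) && !is.null(effect_b)) {
    flip <- effect_a != effect_b
    betas_b[flip] <- -betas_b[flip]
    n_flipped <- sum(flip)
  }
  ok <- is.finite(betas_a) & is.finite(betas_b)
  n <- sum(ok)
  if (n < 3L) stop_arg("fewer than 3 overlapping markers")
  r <- cor(betas_a[ok], betas_b[ok])
  z <- atanh(r)
  zse <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - level) / 2)
  list(r = r, ci = tanh(c(z - q * zse, z + q * zse)), n = n,
       n_flipped = n_flipped)
}
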