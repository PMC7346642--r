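## Shared fixture builders; everything is generated in code at test time.

## minimal summary-statistics frame over a given set of markers
make_sumstats <- function(id, beta, se, p = NULL, chrom = "1",
                          pos = seq_along(id) * 1000L,
                          effect_allele = "A", other_allele = "G",
                          eaf = 0.3, n = 1000L) {
  z <- beta / se
  protarch:::new_sumstats(id, chrom, pos, effect_allele, other_allele, eaf,
                          beta, se, p %||% pmax(2 * pnorm(-abs(z)), 1e-320), n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## small genotype object built from an explicit dosage matrix
make_genotypes <- function(dos, chrom = "1", pos = NULL) {
  dos <- as.matrix(dos)
  if (is.null(colnames(dos))) colnames(dos) <- paste0("s", seq_len(ncol(dos)))
  if (is.null(rownames(dos))) rownames(dos) <- paste0("i", seq_len(nrow(dos)))
  eaf <- colMeans(dos) / 2
  structure(list(
    dosages = dos,
    snp_map = data.frame(snp_id = colnames(dos), chrom = chrom,
                         pos = pos %||% seq_len(ncol(dos)) * 1000L,
                         effect_allele = "A", other_allele = "G",
                         maf = pmin(eaf, 1 - eaf), stringsAsFactors = FALSE)),
    class = "genotypes")
}

## exact log marginal likelihood of y under N(0, sigma_e I + v X_S X_S')
## (used as the enumeration oracle for the 2-marker sampler check)
logml_config <- function(y, X, S, v, sigma_e) {
  n <- length(y)
  V <- diag(sigma_e, n)
  if (length(S)) {
    Xs <- X[, S, drop = FALSE]
    V <- V + v * tcrossprod(Xs)
  }
  ch <- chol(V)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, y, transpose = TRUE)^2))
}
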