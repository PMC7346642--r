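#' Simulate a dosage genotype matrix with block linkage disequilibrium
#'
#' Generates biallelic genotypes as the sum of two haplotypes. Within an LD
#' block each haplotype copies the allelic state of the previous SNP with
#' probability `ld_decay` and is otherwise redrawn from its own allele
#' frequency (a first-order Markov copying model); blocks are mutually
#' independent. `ld_decay = 1` makes a block a set of perfect proxies
#' (pairwise r-squared of 1), `ld_decay = 0` gives independent SNPs.
#'
#' @param n number of individuals (>= 2).
#' @param m number of SNPs (>= 1).
#' @param maf_range length-2 interval in (0, 0.5] from which per-SNP allele
#'   frequencies are drawn uniformly.
#' @param ld_block_size number of adjacent SNPs per LD block.
#' @param ld_decay haplotype copying probability in \[0, 1\].
#' @param chrom chromosome label for the marker map.
#' @param pos_spacing base-pair gap between adjacent SNPs (positions are
#'   strictly increasing).
#' @param seed optional integer seed; a fixed seed makes the draw
#'   bit-reproducible.
#' @return an object of class `"genotypes"`: a list with `dosages`
#'   (n x m matrix with values in \{0, 1, 2\}, sample ids in rownames) and
#'   `snp_map` (data frame: snp_id, chrom, pos, effect_allele, other_allele,
#'   maf). The mapped `maf` is the realised folded allele frequency computed
#'   from the dosages.
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5),
                               ld_block_size = 10L, ld_decay = 0.8,
                               chrom = "1", pos_spacing = 5000L, seed = NULL) {
  n <- check_count(n, "n", min = 2L)
  m <- check_count(m, "m", min = 1L)
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      maf_range[1] > maf_range[2] || maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop_arg("`maf_range` must be an interval within (0, 0.5]")
  check_count(ld_block_size, "ld_block_size")
  check_number(ld_decay, "ld_decay", 0, 1)
  if (!is.null(seed)) set.seed(seed)

  freq <- runif(m, maf_range[1], maf_range[2])
  hap1 <- matrix(0L, n, m)
  hap2 <- matrix(0L, n, m)
  block <- (seq_len(m) - 1L) %/% ld_block_size
  for (j in seq_len(m)) {
    if (j == 1L || block[j] != block[j - 1L]) {
      hap1[, j] <- rbinom(n, 1L, freq[j])
      hap2[, j] <- rbinom(n, 1L, freq[j])
    } else {
      copy1 <- runif(n) < ld_decay
      copy2 <- runif(n) < ld_decay
      hap1[, j] <- ifelse(copy1, hap1[, j - 1L], rbinom(n, 1L, freq[j]))
      hap2[, j] <- ifelse(copy2, hap2[, j - 1L], rbinom(n, 1L, freq[j]))
    }
  }
  dos <- hap1 + hap2
  snp_ids <- sprintf("snp%05d", seq_len(m))
  sample_ids <- sprintf("id%05d", seq_len(n))
  dimnames(dos) <- list(sample_ids, snp_ids)
  eaf <- colMeans(dos) / 2
  map <- data.frame(snp_id = snp_ids, chrom = chrom,
                    pos = as.integer(seq_len(m)) * as.integer(pos_spacing),
                    effect_allele = "A", other_allele = "G",
                    maf = unname(pmin(eaf, 1 - eaf)), stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(list(dosages = dos, snp_map = map), class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat("Genotype dosage matrix:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "SNPs\n")
  cat("MAF range:", sprintf("%.3f-%.3f", min(x$snp_map$maf), max(x$snp_map$maf)), "\n")
  invisible(x)
}

#' Simulate array methylation values with cellular and technical structure
#'
#' Each probe is built as probe intercept + cell-proportion loading + batch
#' shift + (for designated smoking-reactive probes) a smoking effect +
#' Gaussian noise, on a continuous unbounded M-value-like scale. Individual
#' cell proportions are Dirichlet draws (rows sum to one), emulating
#' deconvolution-estimated white-blood-cell proportions supplied as
#' covariates to downstream models.
#'
#' @param n number of individuals.
#' @param m number of CpG probes.
#' @param n_cell_types number of cell types in the proportion simplex.
#' @param batch_levels number of processing-batch levels.
#' @param smoking_prevalence probability an individual is a smoker, in \[0, 1\].
#' @param n_smoking_probes number of leading probes that react to smoking.
#' @param smoking_effect shift added to smoking-reactive probes in smokers
#'   (negative values mimic hypomethylation at smoking loci).
#' @param noise_sd residual probe noise standard deviation.
#' @param seed optional integer seed.
#' @return list with `methylation` (class `"methylation"`: `values` n x m
#'   matrix, `cpg_map` data frame with probe_id/chrom/pos) and `covariates`
#'   (data frame: sample_id, cell-proportion columns summing to 1, batch
#'   factor, smoking indicator).
#' @export
simulate_methylation <- function(n, m, n_cell_types = 5L, batch_levels = 3L,
                                 smoking_prevalence = 0.3,
                                 n_smoking_probes = max(1L, round(0.01 * m)),
                                 smoking_effect = -2,
                                 noise_sd = 1, seed = NULL) {
  n <- check_count(n, "n")
  m <- check_count(m, "m")
  n_cell_types <- check_count(n_cell_types, "n_cell_types")
  batch_levels <- check_count(batch_levels, "batch_levels")
  check_number(smoking_prevalence, "smoking_prevalence", 0, 1)
  n_smoking_probes <- check_count(n_smoking_probes, "n_smoking_probes", min = 0L)
  if (!is.null(seed)) set.seed(seed)

  ## Dirichlet via normalised gammas; one dominant cell type, as in blood
  alpha <- c(6, rep(2, n_cell_types - 1L))[seq_len(n_cell_types)]
  g <- matrix(rgamma(n * n_cell_types, shape = rep(alpha, each = n)), n, n_cell_types)
  props <- g / rowSums(g)
  colnames(props) <- paste0("cell", seq_len(n_cell_types))

  batch <- factor(sample(seq_len(batch_levels), n, replace = TRUE))
  smoking <- rbinom(n, 1L, smoking_prevalence)

  mu <- rnorm(m, 0, 1)
  loadings <- matrix(rnorm(m * n_cell_types, 0, 0.7), m, n_cell_types)
  batch_shift <- matrix(rnorm(batch_levels * m, 0, 0.3), batch_levels, m)
  smk <- numeric(m)
  if (n_smoking_probes > 0L) smk[seq_len(min(n_smoking_probes, m))] <- smoking_effect

  vals <- matrix(rnorm(n * m, 0, noise_sd), n, m)
  vals <- vals + rep(mu, each = n) + props %*% t(loadings) +
    batch_shift[as.integer(batch), , drop = FALSE] + outer(smoking, smk)

  cpg_ids <- sprintf("cg%07d", seq_len(m))
  sample_ids <- sprintf("id%05d", seq_len(n))
  dimnames(vals) <- list(sample_ids, cpg_ids)
  cpg_map <- data.frame(probe_id = cpg_ids, chrom = "1",
                        pos = as.integer(seq_len(m)) * 1000L,
                        stringsAsFactors = FALSE)
  covariates <- data.frame(sample_id = sample_ids, props, batch = batch,
                           smoking = smoking, stringsAsFactors = FALSE)
  meth <- structure(list(values = vals, cpg_map = cpg_map,
                         smoking_probes = cpg_ids[smk != 0]),
                    class = "methylation")
  list(methylation = meth, covariates = covariates)
}

#' @export
print.methylation <- function(x, ...) {
  cat("Methylation matrix:", nrow(x$values), "individuals x",
      ncol(x$values), "CpG probes\n")
  invisible(x)
}

#' Specify a target architecture for simulated protein levels
#'
#' @param n_causal_snps,n_causal_cpgs number of causal markers per group.
#' @param h2_genetic,h2_methylation target variance fractions in \[0, 1\]
#'   (their sum must not exceed 1).
#' @param snp_component_probs,cpg_component_probs mixing proportions over the
#'   effect-size classes from which causal effects are drawn.
#' @param snp_component_vars,cpg_component_vars relative variances of those
#'   classes (effects are rescaled afterwards to hit the target shares, so
#'   only the ratios matter).
#' @param confounder_effects named numeric vector of effects of (numeric)
#'   covariate columns on the protein, e.g. `c(smoking = 0.3)`.
#' @return list of class `"protein_architecture"`.
#' @export
protein_architecture <- function(n_causal_snps = 10L, n_causal_cpgs = 10L,
                                 h2_genetic = 0.3, h2_methylation = 0.2,
                                 snp_component_probs = c(0.5, 0.5),
                                 snp_component_vars = c(0.01, 0.1),
                                 cpg_component_probs = c(1/3, 1/3, 1/3),
                                 cpg_component_vars = c(0.001, 0.01, 0.1),
                                 confounder_effects = NULL) {
  check_number(h2_genetic, "h2_genetic", 0, 1)
  check_number(h2_methylation, "h2_methylation", 0, 1)
  if (h2_genetic + h2_methylation > 1)
    stop_arg("target variance shares sum to more than 1")
  structure(list(n_causal_snps = check_count(n_causal_snps, "n_causal_snps", 0L),
                 n_causal_cpgs = check_count(n_causal_cpgs, "n_causal_cpgs", 0L),
                 h2_genetic = h2_genetic, h2_methylation = h2_methylation,
                 snp_component_probs = snp_component_probs,
                 snp_component_vars = snp_component_vars,
                 cpg_component_probs = cpg_component_probs,
                 cpg_component_vars = cpg_component_vars,
                 confounder_effects = confounder_effects),
            class = "protein_architecture")
}

## draw a causal effect vector: class membership per mixture proportions,
## effect ~ N(0, class variance); rescaled later on realised variance
draw_effects <- function(k, probs, vars) {
  cls <- sample.int(length(probs), k, replace = TRUE, prob = probs)
  list(effects = rnorm(k, 0, sqrt(vars[cls])), class = cls)
}

## rescale a linear predictor to a realised variance target
rescale_component <- function(x, effects, target) {
  v <- var(x)
  if (target == 0 || v == 0) return(list(x = x * 0, effects = effects * 0))
  f <- sqrt(target / v)
  list(x = x * f, effects = effects * f)
}

#' Simulate protein levels from genetic, epigenetic and covariate effects
#'
#' Builds a standardised protein phenotype as the sum of a genetic component
#' (causal SNPs with mixture-distributed effect sizes), a methylation
#' component, optional covariate (confounder) effects and Gaussian noise.
#' Effects are rescaled on their realised (empirical) variances so the
#' recorded variance fractions match the targets by construction; the
#' phenotype is then standardised to unit variance.
#'
#' @param genotypes a `"genotypes"` object (see [simulate_genotypes()]).
#' @param methylation a `"methylation"` object or `NULL`.
#' @param covariates covariate data frame aligned with the genotypes (only
#'   needed when `arch$confounder_effects` is non-empty).
#' @param arch a [protein_architecture()] specification.
#' @param seed optional integer seed.
#' @return list with `protein` (named numeric vector, variance 1) and
#'   `truth` (class `"true_architecture"`): causal ids, effect sizes on the
#'   standardised phenotype scale, realised variance fractions
#'   `true_h2_genetic` / `true_h2_methylation`, confounder effects and seed.
#' @export
simulate_proteins <- function(genotypes, methylation = NULL, covariates = NULL,
                              arch = protein_architecture(), seed = NULL) {
  if (!inherits(arch, "protein_architecture"))
    stop_arg("`arch` must be a protein_architecture()")
  if (!is.null(seed)) set.seed(seed)
  G <- genotypes$dosages
  n <- nrow(G)
  ids <- rownames(G)
  if (!is.null(methylation)) {
    if (!identical(rownames(methylation$values), ids))
      stop_arg("sample ids of genotypes and methylation are not aligned")
  }
  if (!is.null(covariates) && !identical(as.character(covariates$sample_id), ids))
    stop_arg("sample ids of covariates are not aligned with genotypes")

  ## genetic component (on column-standardised dosages so effect scale is per SD)
  causal_snps <- character(0); snp_eff <- numeric(0); snp_cls <- integer(0)
  g_comp <- numeric(n)
  if (arch$h2_genetic > 0 && arch$n_causal_snps > 0) {
    k <- min(arch$n_causal_snps, ncol(G))
    causal_snps <- sample(colnames(G), k)
    dr <- draw_effects(k, arch$snp_component_probs, arch$snp_component_vars)
    Xc <- standardize_columns(G[, causal_snps, drop = FALSE])
    sc <- rescale_component(drop(Xc %*% dr$effects), dr$effects, arch$h2_genetic)
    g_comp <- sc$x; snp_eff <- sc$effects; snp_cls <- dr$class
  }

  m_comp <- numeric(n)
  causal_cpgs <- character(0); cpg_eff <- numeric(0); cpg_cls <- integer(0)
  if (!is.null(methylation) && arch$h2_methylation > 0 && arch$n_causal_cpgs > 0) {
    M <- methylation$values
    k <- min(arch$n_causal_cpgs, ncol(M))
    causal_cpgs <- sample(colnames(M), k)
    dr <- draw_effects(k, arch$cpg_component_probs, arch$cpg_component_vars)
    Mc <- standardize_columns(M[, causal_cpgs, drop = FALSE])
    sc <- rescale_component(drop(Mc %*% dr$effects), dr$effects, arch$h2_methylation)
    m_comp <- sc$x; cpg_eff <- sc$effects; cpg_cls <- dr$class
  }

  conf_comp <- numeric(n)
  ce <- arch$confounder_effects
  if (!is.null(ce) && length(ce)) {
    if (is.null(covariates)) stop_arg("confounder effects given but no covariates")
    for (nm in names(ce)) {
      col <- covariates[[nm]]
      if (is.null(col) || !is.numeric(col))
        stop_arg("confounder `", nm, "` is not a numeric covariate column")
      conf_comp <- conf_comp + ce[[nm]] * col
    }
  }

  noise_target <- 1 - arch$h2_genetic - arch$h2_methylation - var(conf_comp)
  if (noise_target <= 0)
    stop_arg("variance targets plus confounder variance reach or exceed 1")
  e <- rnorm(n)
  e <- e * sqrt(noise_target / var(e))

  y <- g_comp + m_comp + conf_comp + e
  s <- sd(y)
  y <- (y - mean(y)) / s
  names(y) <- ids

  truth <- structure(list(
    causal_snp_ids = causal_snps,
    causal_cpg_ids = causal_cpgs,
    snp_effects = setNames(snp_eff / s, causal_snps),
    cpg_effects = setNames(cpg_eff / s, causal_cpgs),
    snp_classes = snp_cls, cpg_classes = cpg_cls,
    true_h2_genetic = var(g_comp) / s^2,
    true_h2_methylation = var(m_comp) / s^2,
    confounder_effects = if (is.null(ce)) list() else as.list(ce / s),
    seed = seed), class = "true_architecture")
  list(protein = y, truth = truth)
}

#' Simulate a pair of regional summary-statistic sets
#'
#' Draws two z-score vectors over the same LD region from the standard
#' multivariate-normal model for marginal GWAS statistics:
#' `z ~ MVN(sqrt(n) * R b, R)` where `R` is the dosage correlation matrix of
#' a simulated reference panel and `b` the standardised causal effect(s).
#' Used to exercise colocalisation under known causal-variant sharing.
#'
#' @param scenario one of `"shared_causal"` (the same SNP drives both
#'   traits), `"distinct_causal"` (two causal SNPs in low LD),
#'   `"one_trait_only"` (trait 1 only), `"no_signal"`.
#' @param n_snps number of SNPs in the region (>= 10).
#' @param n1,n2 GWAS sample sizes of the two traits.
#' @param z_causal expected z-score at the causal SNP(s).
#' @param ld_block_size,ld_decay LD structure of the reference panel
#'   (see [simulate_genotypes()]).
#' @param n_ref reference-panel size used to estimate the LD matrix.
#' @param max_r2_distinct maximum LD r-squared allowed between the two
#'   causal SNPs in the `distinct_causal` scenario.
#' @param seed optional integer seed.
#' @return list with `stats1`, `stats2` (summary-statistic data frames with
#'   internally consistent `beta = z * se`, `se = 1/sqrt(n)`), `ld` (SNP
#'   correlation matrix), and `causal` (list naming the causal SNP per trait).
#' @export
simulate_summary_pair <- function(scenario = c("shared_causal", "distinct_causal",
                                               "one_trait_only", "no_signal"),
                                  n_snps = 500L, n1 = 10000L, n2 = 10000L,
                                  z_causal = 12, ld_block_size = 25L,
                                  ld_decay = 0.9, n_ref = 1000L,
                                  max_r2_distinct = 0.05, seed = NULL) {
  scenario <- match.arg(scenario)
  n_snps <- check_count(n_snps, "n_snps", min = 10L)
  if (!is.null(seed)) set.seed(seed)

  ref <- simulate_genotypes(n_ref, n_snps, maf_range = c(0.1, 0.5),
                            ld_block_size = ld_block_size, ld_decay = ld_decay)
  R <- cor(ref$dosages)
  ## ridge so the Cholesky factor exists despite near-perfect proxies
  Rc <- R * (n_ref / (n_ref + 2)) + diag(2 / (n_ref + 2), n_snps)
  U <- chol(Rc)

  c1 <- c2 <- NA_integer_
  mid <- n_snps %/% 2L
  if (scenario %in% c("shared_causal", "one_trait_only")) {
    c1 <- mid
    if (scenario == "shared_causal") c2 <- mid
  } else if (scenario == "distinct_causal") {
    c1 <- mid
    cand <- which(R[c1, ]^2 < max_r2_distinct)
    if (!length(cand)) stop_arg("no SNP in sufficiently low LD with the first causal SNP")
    c2 <- cand[which.min(abs(cand - (mid + n_snps %/% 4L)))]
  }
  mu1 <- if (is.na(c1)) numeric(n_snps) else z_causal * R[, c1]
  mu2 <- if (is.na(c2)) numeric(n_snps) else z_causal * R[, c2]
  z1 <- drop(mu1 + crossprod(U, rnorm(n_snps)))
  z2 <- drop(mu2 + crossprod(U, rnorm(n_snps)))

  mk <- function(z, n) {
    se <- rep(1 / sqrt(n), n_snps)
    new_sumstats(ref$snp_map$snp_id, ref$snp_map$chrom, ref$snp_map$pos,
                 ref$snp_map$effect_allele, ref$snp_map$other_allele,
                 colMeans(ref$dosages) / 2, z * se, se,
                 clamp_p(2 * pnorm(-abs(z))), n)
  }
  list(stats1 = mk(z1, n1), stats2 = mk(z2, n2), ld = R,
       causal = list(trait1 = if (is.na(c1)) NA_character_ else ref$snp_map$snp_id[c1],
                     trait2 = if (is.na(c2)) NA_character_ else ref$snp_map$snp_id[c2]))
}
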