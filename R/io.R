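## Readers and writers for the tabular interchange formats: dosage matrices
## with sidecar maps, GWAS-style summary statistics, sample-by-marker
## matrices, ground-truth architectures (JSON), run configuration (YAML)
## and BED export. Coordinates are 1-based inclusive everywhere internally;
## only bed_export() converts to 0-based half-open. Missing values are "NA".

#' Write genotypes as a dosage TSV with a sidecar map
#'
#' Produces `<prefix>.dosage.tsv` (sample_id column then one column per
#' SNP) and `<prefix>.map.tsv` (snp_id, chrom, pos, effect_allele,
#' other_allele, maf).
#'
#' @param genotypes a `"genotypes"` object.
#' @param prefix output path prefix.
#' @return the two file paths, invisibly.
#' @export
write_dosage <- function(genotypes, prefix) {
  dos_path <- paste0(prefix, ".dosage.tsv")
  map_path <- paste0(prefix, ".map.tsv")
  df <- data.frame(sample_id = rownames(genotypes$dosages),
                   genotypes$dosages, check.names = FALSE)
  write.table(df, dos_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(genotypes$snp_map, map_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(dosages = dos_path, map = map_path))
}

#' Read genotypes from a dosage TSV and sidecar map
#'
#' Validates that dosages lie in \[0, 2\], that sample and marker ids are
#' unique, and that the map matches the dosage columns.
#'
#' @param prefix path prefix used by [write_dosage()], or a dosage file
#'   path with `map` given explicitly.
#' @param map optional explicit map path.
#' @return a `"genotypes"` object.
#' @export
read_dosage <- function(prefix, map = NULL) {
  dos_path <- if (is.null(map)) paste0(prefix, ".dosage.tsv") else prefix
  map_path <- map %||% paste0(prefix, ".map.tsv")
  if (!file.exists(dos_path)) stop_arg("no such file: ", dos_path)
  df <- read.table(dos_path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  smap <- read.table(map_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE,
                     colClasses = c(snp_id = "character", chrom = "character",
                                    effect_allele = "character",
                                    other_allele = "character"))
  if (anyDuplicated(df$sample_id)) stop_arg("duplicate sample ids")
  dos <- as.matrix(df[, -1L, drop = FALSE])
  rownames(dos) <- df$sample_id
  if (anyDuplicated(colnames(dos))) stop_arg("duplicate marker ids")
  bad <- which(!is.na(dos) & (dos < 0 | dos > 2), arr.ind = TRUE)
  if (nrow(bad))
    stop_arg("dosage outside [0, 2] at data line ", bad[1L, 1L],
             ", marker ", colnames(dos)[bad[1L, 2L]])
  if (!identical(smap$snp_id, colnames(dos)))
    stop_arg("map snp_id column does not match dosage columns")
  structure(list(dosages = dos, snp_map = smap), class = "genotypes")
}

#' Read genotype dosages from a VCF
#'
#' Converts GT fields to effect-allele (ALT) dosages 0/1/2 via the vcfR
#' package; missing genotypes become `NA`.
#'
#' @param path VCF file path (uncompressed or gzipped).
#' @return a `"genotypes"` object.
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_arg("package `vcfR` is required for VCF input")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    out <- rep(NA_real_, length(g))
    ok <- !is.na(g) & !grepl(".", g, fixed = TRUE)
    out[ok] <- vapply(strsplit(g[ok], "[/|]"),
                      function(a) sum(a == "1") + 0, 0)
    out
  }
  dos <- matrix(count_alt(as.vector(gt)), nrow(gt), ncol(gt),
                dimnames = dimnames(gt))
  fx <- vcfR::getFIX(v)
  ids <- ifelse(is.na(fx[, "ID"]) | fx[, "ID"] == ".",
                paste0(fx[, "CHROM"], ":", fx[, "POS"]), fx[, "ID"])
  dos <- t(dos)  # individuals x SNPs
  colnames(dos) <- ids
  eaf <- colMeans(dos, na.rm = TRUE) / 2
  map <- data.frame(snp_id = ids, chrom = fx[, "CHROM"],
                    pos = as.integer(fx[, "POS"]),
                    effect_allele = fx[, "ALT"], other_allele = fx[, "REF"],
                    maf = pmin(eaf, 1 - eaf), stringsAsFactors = FALSE)
  structure(list(dosages = dos, snp_map = map), class = "genotypes")
}

#' Write summary statistics in the canonical GWAS TSV layout
#'
#' Fixed header `snp_id chr pos a1 a2 freq b se p n`; rows ordered by
#' (chrom, pos); numbers at full precision with p in scientific notation.
#' Zero p-values are clamped to 1e-320 with a warning.
#'
#' @param stats summary-statistics data frame.
#' @param path output path.
#' @export
write_sumstats <- function(stats, path) {
  check_sumstats(stats)
  if (any(stats$p == 0, na.rm = TRUE)) {
    warning("p = 0 clamped to 1e-320")
    stats$p <- clamp_p(stats$p)
  }
  stats <- stats[order(stats$chrom, stats$pos), , drop = FALSE]
  out <- data.frame(snp_id = stats$id, chr = stats$chrom, pos = stats$pos,
                    a1 = stats$effect_allele, a2 = stats$other_allele,
                    freq = format(stats$eaf, digits = 17, trim = TRUE),
                    b = format(stats$beta, digits = 17, trim = TRUE),
                    se = format(stats$se, digits = 17, trim = TRUE),
                    p = format(stats$p, digits = 17, scientific = TRUE, trim = TRUE),
                    n = stats$n, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read summary statistics written by [write_sumstats()]
#'
#' @param path TSV path.
#' @return summary-statistics data frame with canonical column names.
#' @export
read_sumstats <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(snp_id = "character", chr = "character",
                                  a1 = "character", a2 = "character"))
  new_sumstats(df$snp_id, df$chr, df$pos, df$a1, df$a2, df$freq, df$b,
               df$se, df$p, df$n)
}

#' Write a sample-by-marker matrix as TSV
#'
#' Header row of sample ids; first column holds marker ids (transposed
#' marker x sample layout, the convention for methylation and protein
#' matrices).
#'
#' @param x matrix with sample rownames and marker colnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(x, path) {
  m <- t(as.matrix(x))
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path TSV path.
#' @return numeric matrix, samples in rows.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  t(m)
}

#' Serialise a ground-truth architecture to JSON
#'
#' @param truth a `"true_architecture"` from [simulate_proteins()].
#' @param path output JSON path.
#' @export
write_architecture <- function(truth, path) {
  if (!inherits(truth, "true_architecture"))
    stop_arg("`truth` must be a true_architecture")
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a ground-truth architecture from JSON
#'
#' @param path JSON path written by [write_architecture()].
#' @return a `"true_architecture"` object.
#' @export
read_architecture <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$causal_snp_ids <- as.character(x$causal_snp_ids)
  x$causal_cpg_ids <- as.character(x$causal_cpg_ids)
  x$snp_effects <- setNames(as.numeric(x$snp_effects), x$causal_snp_ids)
  x$cpg_effects <- setNames(as.numeric(x$cpg_effects), x$causal_cpg_ids)
  x$snp_classes <- as.integer(x$snp_classes)
  x$cpg_classes <- as.integer(x$cpg_classes)
  structure(x, class = "true_architecture")
}

#' Export loci to BED
#'
#' Converts 1-based inclusive positions to BED's 0-based half-open
#' intervals: a single base at position `pos` becomes `(pos - 1, pos]`.
#'
#' @param df data frame with `chrom` and `pos` columns (and optionally
#'   `id`, used as the BED name field).
#' @param path output BED path.
#' @export
bed_export <- function(df, path) {
  if (!all(c("chrom", "pos") %in% names(df)))
    stop_arg("`df` needs chrom and pos columns")
  bed <- data.frame(chrom = df$chrom, start = df$pos - 1L, end = df$pos,
                    name = df$id %||% ".")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

run_config_keys <- list(
  seed = "integer", genomewide_alpha_snp = "numeric",
  genomewide_alpha_cpg = "numeric", n_phenotypes = "integer",
  pip_threshold = "numeric", n_iter = "integer", burn_in = "integer",
  thin = "integer", snp_component_variances = "numeric",
  cpg_component_variances = "numeric", combined_component_variances = "numeric",
  rank_offset = "character", lod_max_below_frac = "numeric",
  cis_window_bp = "integer", ld_concordance_r2 = "numeric",
  mr_prune_r2 = "numeric", coloc_flank_bp = "integer",
  coloc_p1 = "numeric", coloc_p2 = "numeric", coloc_p12 = "numeric",
  coloc_prior_sd = "numeric", paths = "list")

#' Read a YAML run configuration
#'
#' Validates the file against the known parameter schema: unknown keys are
#' rejected, and a `seed` entry is required so every random stage is
#' explicitly seeded.
#'
#' @param path YAML path.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(run_config_keys))
  if (length(unknown))
    stop_arg("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop_arg("configuration must set an explicit `seed`")
  cfg
}

#' Write a provenance record for a run
#'
#' JSON record of the configuration, seed, package version and input-file
#' checksums, sufficient to reproduce the run.
#'
#' @param path output JSON path.
#' @param config configuration list (e.g. from [read_run_config()]).
#' @param inputs character vector of input file paths to checksum.
#' @export
write_provenance <- function(path, config, inputs = character(0)) {
  rec <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("protarch")),
    r_version = R.version.string,
    config = config,
    input_checksums = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
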