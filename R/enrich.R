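#' Gene-set collection with an explicit universe
#'
#' @param sets named list of character vectors of gene ids; every set must
#'   be a subset of the universe and contain no duplicates.
#' @param universe character vector of all testable gene ids (the null set).
#' @return object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop_arg("`sets` must be a named list")
  universe <- unique(as.character(universe))
  if (!length(universe)) stop_arg("empty universe")
  for (nm in names(sets)) {
    s <- as.character(sets[[nm]])
    if (anyDuplicated(s)) stop_arg("duplicate ids in set `", nm, "`")
    if (!all(s %in% universe))
      stop_arg("set `", nm, "` contains ids outside the universe")
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member ids.
#'
#' @param path GMT file path.
#' @param universe universe gene ids; defaults to the union of all sets.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  gene_set_collection(sets, universe %||% unique(unlist(sets)))
}

#' Write gene sets to a GMT file
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test of hit genes
#'
#' For each gene set, the upper-tail hypergeometric probability
#' `P(X >= overlap)` of drawing at least the observed overlap when `|hits|`
#' genes are sampled without replacement from a universe containing
#' `|set|` successes. Hits outside the universe are dropped with a warning.
#'
#' @param hit_genes character vector of significant gene ids.
#' @param collection a [gene_set_collection()].
#' @param correction multiple-testing adjustment over the tested sets:
#'   `"bh"` (Benjamini-Hochberg, default) or `"bonferroni"`.
#' @return data frame (set, set_size, overlap, expected, p, p_adjusted)
#'   sorted by ascending p.
#' @export
hypergeom_enrich <- function(hit_genes, collection,
                             correction = c("bh", "bonferroni")) {
  correction <- match.arg(correction)
  if (!inherits(collection, "gene_set_collection"))
    stop_arg("`collection` must be a gene_set_collection")
  hit_genes <- unique(as.character(hit_genes))
  if (!length(hit_genes)) stop_arg("empty hit list")
  outside <- setdiff(hit_genes, collection$universe)
  if (length(outside)) {
    warning(length(outside), " hit gene(s) outside the universe dropped")
    hit_genes <- setdiff(hit_genes, outside)
    if (!length(hit_genes)) stop_arg("no hits remain inside the universe")
  }
  N <- length(collection$universe)
  n <- length(hit_genes)
  res <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    K <- length(set)
    k <- length(intersect(hit_genes, set))
    data.frame(set = nm, set_size = K, overlap = k, expected = n * K / N,
               p = phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- p.adjust(out$p, method = if (correction == "bh") "BH" else "bonferroni")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
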