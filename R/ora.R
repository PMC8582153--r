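#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name <tab> description <tab> gene ...`.
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short))
    stop("malformed GMT line ", which(short)[1], ": fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in ", path)
  sets
}

#' Build a gene-set collection against a universe
#'
#' Intersects every set with the universe; sets that become empty are
#' dropped with a warning.
#'
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of all eligible gene ids (typically the
#'   expressed universe: genes passing the CPM filter).
#' @return list with `sets` (trimmed) and `universe`.
#' @export
gene_set_collection <- function(sets, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  trimmed <- lapply(sets, intersect, universe)
  empty <- lengths(trimmed) == 0
  if (any(empty))
    warning(sum(empty), " gene set(s) empty after universe intersection; dropped")
  structure(list(sets = trimmed[!empty], universe = universe),
            class = "GeneSetCollection")
}

#' Hypergeometric over-representation analysis
#'
#' For each set of size K in a universe of size N, with a query of size n
#' overlapping the set in k genes, computes the upper-tail hypergeometric
#' probability `P(X >= k)` and BH-adjusts across all sets in the
#' collection. Query genes outside the universe are reported and dropped.
#'
#' @param query Character vector of gene ids.
#' @param collection A collection from [gene_set_collection()].
#' @return data.frame with `set`, `set_size`, `overlap`, `expected`, `p`,
#'   `adj_p`, ordered by p.
#' @export
hypergeometric_ora <- function(query, collection) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  query <- unique(as.character(query))
  if (length(query) == 0) stop("empty query set")
  outside <- setdiff(query, collection$universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, collection$universe)
    if (length(query) == 0) stop("no query genes inside the universe")
  }
  N <- length(collection$universe)
  n <- length(query)
  res <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    K <- length(set)
    k <- length(intersect(query, set))
    data.frame(set = nm, set_size = K, overlap = k,
               expected = n * K / N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
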