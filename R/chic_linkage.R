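#' Read an enhancer-promoter interaction map
#'
#' Reads a BEDPE-like TSV with at least seven columns: the enhancer anchor
#' (`chrom1`, `start1`, `end1`), the promoter anchor (`chrom2`, `start2`,
#' `end2`) and a comma-separated list of gene ids annotated to the promoter
#' anchor. Coordinates are 0-based half-open. If the gene labels sit on the
#' first anchor instead, the pair is flipped so that the labelled anchor is
#' always the promoter side. Rows with an empty gene field or inverted
#' anchors are rejected with a warning.
#'
#' @param path Path to the interaction TSV. A header line is detected and
#'   skipped.
#' @param genes_on Which anchor carries the gene labels: `"second"`
#'   (default, standard orientation), `"first"`, or `"auto"`.
#' @return An `InteractionMap`: a list with `pairs` (data.frame) and
#'   `enhancers` (a `GRanges` overlap index over the enhancer anchors,
#'   mcols `pair_id`).
#' @export
read_interaction_map <- function(path, genes_on = c("second", "first", "auto")) {
  genes_on <- match.arg(genes_on)
  if (!file.exists(path)) stop("interaction map not found: ", path)
  first <- readLines(path, n = 1)
  has_header <- grepl("chrom|start|gene", first, ignore.case = TRUE)
  tab <- read.delim(path, header = FALSE, skip = as.integer(has_header),
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 7)
    stop("interaction map needs 7+ columns ",
         "(chrom1,start1,end1,chrom2,start2,end2,genes)")
  names(tab)[1:7] <- c("chrom1", "start1", "end1",
                       "chrom2", "start2", "end2", "genes")
  tab$genes <- trimws(as.character(tab$genes))
  if (genes_on == "first" ||
      (genes_on == "auto" && all(!nzchar(tab$genes)))) {
    tab[, 1:7] <- tab[, c(4, 5, 6, 1, 2, 3, 7)]
  }
  bad_anchor <- tab$start1 >= tab$end1 | tab$start2 >= tab$end2
  empty_gene <- !nzchar(tab$genes) | is.na(tab$genes)
  drop <- bad_anchor | empty_gene
  if (any(drop))
    warning(sum(drop), " interaction record(s) rejected (",
            sum(bad_anchor), " inverted anchors, ",
            sum(empty_gene), " empty gene fields)")
  tab <- tab[!drop, , drop = FALSE]
  if (nrow(tab) == 0) stop("no valid interaction records in ", path)
  tab$target_genes <- lapply(strsplit(tab$genes, ","), trimws)
  tab$pair_id <- seq_len(nrow(tab))
  enh <- GRanges(tab$chrom1, IRanges(tab$start1 + 1L, tab$end1))
  mcols(enh)$pair_id <- tab$pair_id
  structure(list(pairs = tab, enhancers = enh), class = "InteractionMap")
}

#' @export
print.InteractionMap <- function(x, ...) {
  cat("InteractionMap:", nrow(x$pairs), "enhancer-promoter pairs\n")
  invisible(x)
}

#' Write an interaction map back to its TSV form
#'
#' @param map An `InteractionMap`.
#' @param path Output file path.
#' @export
write_interaction_map <- function(map, path) {
  tab <- map$pairs
  out <- data.frame(tab$chrom1, tab$start1, tab$end1,
                    tab$chrom2, tab$start2, tab$end2,
                    vapply(tab$target_genes, paste, "", collapse = ","))
  names(out) <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                  "genes")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign distal peaks to genes via enhancer-promoter interactions
#'
#' A peak is distal-eligible when its midpoint lies farther than `flank` bp
#' from every TSS (`|tss_distance| > flank`; peaks on chromosomes with no
#' annotated TSS are eligible). Each eligible peak overlapping an enhancer
#' anchor by >= 1 bp contributes all of that pair's target genes; the result
#' is the union over eligible peaks.
#'
#' @param peak_annotations Annotated peak `GRanges` from [annotate_peaks()]
#'   (must carry `tss_distance`).
#' @param map An `InteractionMap`.
#' @param flank Promoter half-width in bp (default 3000); peaks within this
#'   distance of a TSS are never routed through enhancers.
#' @return Named list, gene_id -> character vector of supporting peak names.
#' @export
link_distal_peaks <- function(peak_annotations, map, flank = 3000L) {
  if (is.null(mcols(peak_annotations)$tss_distance))
    stop("peaks must be annotated (tss_distance missing); run annotate_peaks")
  dist <- mcols(peak_annotations)$tss_distance
  eligible <- is.na(dist) | abs(dist) > flank
  peaks <- peak_annotations[eligible]
  if (length(peaks) == 0) return(list())
  ov <- suppressWarnings(findOverlaps(peaks, map$enhancers, minoverlap = 1L,
                                      ignore.strand = TRUE))
  if (length(ov) == 0) return(list())
  pair_idx <- mcols(map$enhancers)$pair_id[subjectHits(ov)]
  genes_per_hit <- map$pairs$target_genes[pair_idx]
  peak_names <- mcols(peaks)$name[queryHits(ov)]
  if (is.null(peak_names)) peak_names <- paste0("peak_", queryHits(ov))
  g <- unlist(genes_per_hit, use.names = FALSE)
  p <- rep(peak_names, lengths(genes_per_hit))
  res <- lapply(split(p, g), function(x) sort(unique(x)))
  res[sort(names(res))]
}

#' Genes supported only by distal (enhancer-linked) binding
#'
#' Set difference of the enhancer-linked genes and the promoter-bound gene
#' union: genes that also have a peak in their promoter window are excluded.
#'
#' @param linked_genes Output of [link_distal_peaks()] (or a character
#'   vector of gene ids).
#' @param promoter_gene_union Character vector of promoter-bound gene ids.
#' @return Sorted character vector of distal-only gene ids.
#' @export
distal_only_genes <- function(linked_genes, promoter_gene_union) {
  ids <- if (is.list(linked_genes)) names(linked_genes) else linked_genes
  sort(setdiff(ids, promoter_gene_union))
}
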