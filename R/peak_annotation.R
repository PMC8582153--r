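#' Read ChIP-Seq peak calls from a BED3+ file
#'
#' Reads the first three (and optionally more) BED columns, validates every
#' record, and labels the peaks with their cell line. Column 5 (or column 4
#' if numeric, as in some caller exports) is taken as the peak score when
#' present. BED coordinates are 0-based half-open.
#'
#' @param path Path to a BED3+ file. `track`/`browser`/comment lines are
#'   skipped.
#' @param cell_line Cell-line label attached to every peak.
#' @return A `GRanges` with mcols `cell_line`, `name`, `score`.
#' @export
read_peaks <- function(path, cell_line) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("no peak records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3))
    stop("BED parse error at line ", lineno[which(ncol < 3)[1]],
         ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start0) | is.na(end0)
  if (any(bad))
    stop("BED parse error at line ", lineno[which(bad)[1]],
         ": non-numeric coordinates")
  inv <- start0 >= end0
  if (any(inv))
    stop("invalid peak record at line ", lineno[which(inv)[1]],
         ": start >= end")
  name <- ifelse(ncol >= 4, vapply(fields, function(f)
    if (length(f) >= 4) f[[4]] else NA_character_, ""), NA_character_)
  score <- rep(NA_real_, length(fields))
  has5 <- ncol >= 5
  score[has5] <- suppressWarnings(as.numeric(vapply(fields[has5], `[[`, "", 5L)))
  # some exports put the score in column 4
  alt <- !has5 & ncol == 4
  score[alt] <- suppressWarnings(as.numeric(name[alt]))
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
  mcols(gr)$cell_line <- as.character(cell_line)
  mcols(gr)$name <- ifelse(is.na(name) | !is.na(suppressWarnings(as.numeric(name))) & ncol == 4,
                           paste0(cell_line, "_peak_", seq_along(gr)), name)
  mcols(gr)$score <- score
  gr
}

#' Classify the genomic context of each peak
#'
#' Assigns each peak one of three mutually exclusive contexts with the
#' precedence promoter > intragenic > intergenic: a peak overlapping any
#' promoter window by >= 1 bp is `promoter` (and is assigned to *all* genes
#' whose windows it overlaps); otherwise a peak overlapping any gene body is
#' `intragenic`; otherwise `intergenic`. The nearest gene and the signed
#' distance from the peak midpoint to its TSS are always populated, except
#' for peaks on chromosomes absent from the annotation, which are classified
#' intergenic with a warning and `NA` nearest fields.
#'
#' @param peaks `GRanges` from [read_peaks()].
#' @param annotation The `GenomeAnnotation` the windows were built from.
#' @param windows Promoter windows from [promoter_windows()].
#' @return The peaks `GRanges` with added mcols `context`, `nearest_gene`,
#'   `tss_distance` (signed bp, positive downstream of the TSS) and
#'   `promoter_genes` (a `CharacterList`).
#' @export
annotate_peaks <- function(peaks, annotation, windows) {
  if (length(peaks) == 0) stop("no peaks to annotate")
  known <- as.character(seqnames(peaks)) %in%
    unique(as.character(seqnames(annotation$genes)))
  if (!all(known))
    warning(sum(!known), " peak(s) on chromosomes absent from the annotation;",
            " classified intergenic with NA nearest fields")

  ov_w <- suppressWarnings(findOverlaps(peaks, windows, minoverlap = 1L,
                                        ignore.strand = TRUE))
  promoter_genes <- S4Vectors::splitAsList(
    mcols(windows)$gene_id[subjectHits(ov_w)],
    factor(queryHits(ov_w), levels = seq_along(peaks)))
  promoter_genes <- IRanges::CharacterList(lapply(promoter_genes,
                                                  function(g) sort(unique(g))))
  is_promoter <- lengths(promoter_genes) > 0

  ov_g <- suppressWarnings(findOverlaps(peaks, annotation$genes,
                                        minoverlap = 1L, ignore.strand = TRUE))
  in_gene <- logical(length(peaks))
  in_gene[unique(queryHits(ov_g))] <- TRUE

  context <- unname(ifelse(is_promoter, "promoter",
                           ifelse(in_gene, "intragenic", "intergenic")))
  context[!known] <- "intergenic"
  promoter_genes[!known] <- IRanges::CharacterList(character(0))[rep(1, sum(!known))]

  # midpoint of a 0-based half-open peak
  mid0 <- (start(peaks) - 1L + end(peaks)) %/% 2L
  nt <- nearest_tss(annotation, as.character(seqnames(peaks)), mid0)
  nt$gene_id[!known] <- NA_character_
  nt$distance[!known] <- NA_integer_

  out <- peaks
  mcols(out)$context <- context
  mcols(out)$nearest_gene <- nt$gene_id
  mcols(out)$tss_distance <- nt$distance
  mcols(out)$promoter_genes <- promoter_genes
  out
}

#' Per-cell-line promoter-bound gene sets, union and intersection
#'
#' Collects, for each cell line, the set of genes with at least one peak in
#' their promoter window, the deduplicated union across cell lines, and the
#' genes common to all cell lines.
#'
#' @param annotations A single annotated peak `GRanges` (split internally by
#'   its `cell_line` mcol) or a named list of annotated `GRanges`, one per
#'   cell line.
#' @return list with `per_line` (named list of character vectors), `union`
#'   and `common`.
#' @export
promoter_gene_sets <- function(annotations) {
  if (inherits(annotations, "GRanges"))
    annotations <- split(annotations, mcols(annotations)$cell_line)
  annotations <- as.list(annotations)
  if (length(annotations) == 0) stop("at least one cell line required")
  per_line <- lapply(annotations, function(a)
    sort(unique(unlist(mcols(a)$promoter_genes))))
  union_set <- sort(unique(unlist(per_line)))
  common <- sort(Reduce(intersect, per_line))
  list(per_line = per_line, union = union_set, common = common)
}

#' Fraction of peaks in each genomic context
#'
#' @param annotations Annotated peak `GRanges` (or list of them, pooled).
#' @return Named numeric vector over `promoter`, `intragenic`, `intergenic`
#'   summing to 1.
#' @export
context_distribution <- function(annotations) {
  if (is.list(annotations) && !inherits(annotations, "GRanges"))
    ctx <- unlist(lapply(annotations, function(a) mcols(a)$context))
  else ctx <- mcols(annotations)$context
  if (length(ctx) == 0) stop("no annotated peaks")
  lv <- c("promoter", "intragenic", "intergenic")
  tab <- table(factor(ctx, levels = lv))
  as.numeric(tab) / sum(tab) -> frac
  names(frac) <- lv
  frac
}

#' Write annotated peaks as a TSV
#'
#' One row per peak with 0-based half-open coordinates, context columns and
#' comma-separated promoter gene assignments.
#'
#' @param annotated Annotated peak `GRanges`.
#' @param path Output file path.
#' @export
write_annotated_peaks <- function(annotated, path) {
  df <- data.frame(
    chrom = as.character(seqnames(annotated)),
    start = start(annotated) - 1L,
    end = end(annotated),
    name = mcols(annotated)$name,
    score = mcols(annotated)$score,
    cell_line = mcols(annotated)$cell_line,
    context = mcols(annotated)$context,
    nearest_gene = mcols(annotated)$nearest_gene,
    tss_distance = mcols(annotated)$tss_distance,
    promoter_genes = vapply(mcols(annotated)$promoter_genes,
                            paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
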