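#' @import GenomicRanges IRanges S4Vectors
#' @importFrom GenomeInfoDb seqnames seqlevels
#' @importFrom stats p.adjust pt cor fisher.test phyper median rnbinom rlnorm
#'   rnorm runif rpois var setNames model.matrix complete.cases sd quantile
#' @importFrom utils read.delim write.table head
NULL

#' Read a gene annotation into a genome model
#'
#' Parses gene records from a GTF or BED12 file and builds the coordinate
#' frame used for all peak assignment: one strand-aware TSS per gene, plus a
#' per-chromosome sorted index (a `GRanges`) supporting overlap and
#' nearest-TSS queries.
#'
#' The package-facing coordinate convention (as returned by
#' [annotation_table()] and written to BED) is 0-based half-open; GTF input
#' (1-based closed) and BED input are both converted at this reader
#' boundary. The TSS of a `+` strand gene is its first base, of a `-`
#' strand gene its last covered base. Multi-transcript genes collapse to one
#' record per `gene_id` (only `gene`-typed GTF rows are used when present).
#'
#' @param path Path to the annotation file.
#' @param format Either `"gtf"` or `"bed12"`.
#' @return A `GenomeAnnotation` object: a list with `genes` (a `GRanges`
#'   with mcols `gene_id`, `symbol`, `biotype`, `tss` — the 0-based TSS
#'   position) and `tss` (a width-one `GRanges` at each TSS, same order).
#' @export
read_gene_annotation <- function(path, format = c("gtf", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (file.size(path) == 0) stop("annotation file is empty: ", path)
  if (format == "gtf") {
    gr <- tryCatch(
      rtracklayer::import(path, format = "gtf"),
      error = function(e) stop("GTF parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    if (length(gr) == 0) stop("no records in GTF file: ", path)
    if (is.null(gr$gene_id) || anyNA(gr$gene_id))
      stop("GTF records missing the gene_id attribute")
    if ("type" %in% names(mcols(gr)) && any(gr$type == "gene"))
      gr <- gr[gr$type == "gene"]
    if (anyDuplicated(gr$gene_id))
      stop("duplicate gene_id in annotation: ",
           paste(unique(gr$gene_id[duplicated(gr$gene_id)]), collapse = ", "))
    genes <- GRanges(seqnames(gr), ranges(gr), strand = strand(gr))
    mcols(genes)$gene_id <- gr$gene_id
    sym <- if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
    mcols(genes)$symbol <- ifelse(is.na(sym), gr$gene_id, sym)
    bio <- if (!is.null(gr$gene_type)) gr$gene_type else
      if (!is.null(gr$gene_biotype)) gr$gene_biotype else
        rep("protein_coding", length(gr))
    mcols(genes)$biotype <- ifelse(is.na(bio), "protein_coding", bio)
  } else {
    bed <- tryCatch(
      rtracklayer::import(path, format = "bed"),
      error = function(e) stop("BED12 parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    if (length(bed) == 0) stop("no records in BED file: ", path)
    if (is.null(bed$name) || anyNA(bed$name))
      stop("BED12 records missing the name column")
    if (anyDuplicated(bed$name))
      stop("duplicate gene_id in annotation: ",
           paste(unique(bed$name[duplicated(bed$name)]), collapse = ", "))
    genes <- GRanges(seqnames(bed), ranges(bed), strand = strand(bed))
    mcols(genes)$gene_id <- bed$name
    mcols(genes)$symbol <- bed$name
    mcols(genes)$biotype <- "protein_coding"
  }
  if (any(strand(genes) == "*"))
    stop("unknown strand character in annotation (must be + or -)")
  .new_genome_annotation(genes)
}

# `genes` is a standard 1-based closed GRanges; derives the 0-based TSS and
# the width-one TSS index.
.new_genome_annotation <- function(genes) {
  strand_plus <- as.character(strand(genes)) == "+"
  tss0 <- ifelse(strand_plus, start(genes) - 1L, end(genes) - 1L)
  mcols(genes)$tss <- as.integer(tss0)
  o <- order(as.character(seqnames(genes)), start(genes))
  genes <- genes[o]
  tss <- GRanges(seqnames(genes),
                 IRanges(mcols(genes)$tss + 1L, width = 1L),
                 strand = strand(genes))
  mcols(tss)$gene_id <- mcols(genes)$gene_id
  structure(list(genes = genes, tss = tss), class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", length(x$genes), "genes on",
      length(unique(as.character(seqnames(x$genes)))), "chromosomes\n")
  invisible(x)
}

#' Build a genome annotation from an in-memory gene table
#'
#' Convenience constructor used by the simulator and tests. Input
#' coordinates are 0-based half-open.
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, and optionally `symbol`, `biotype`.
#' @return A `GenomeAnnotation`.
#' @export
genome_annotation <- function(df) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(df)))
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("invalid gene interval: require 0 <= start < end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id")
  genes <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                   strand = df$strand)
  mcols(genes)$gene_id <- as.character(df$gene_id)
  mcols(genes)$symbol <- if (!is.null(df$symbol)) as.character(df$symbol) else
    as.character(df$gene_id)
  mcols(genes)$biotype <- if (!is.null(df$biotype)) as.character(df$biotype) else
    "protein_coding"
  .new_genome_annotation(genes)
}

#' Extract the gene table from a genome annotation
#'
#' @param annotation A `GenomeAnnotation`.
#' @return data.frame with one row per gene; `start`, `end` and `tss` are
#'   0-based half-open.
#' @export
annotation_table <- function(annotation) {
  g <- annotation$genes
  data.frame(
    gene_id = mcols(g)$gene_id,
    symbol = mcols(g)$symbol,
    chrom = as.character(seqnames(g)),
    start = start(g) - 1L,
    end = end(g),
    strand = as.character(strand(g)),
    tss = mcols(g)$tss,
    biotype = mcols(g)$biotype,
    stringsAsFactors = FALSE
  )
}

#' Write an annotation as BED12
#'
#' Single-exon BED12 records, one per gene; the inverse of
#' `read_gene_annotation(format = "bed12")`.
#'
#' @param annotation A `GenomeAnnotation`.
#' @param path Output file path.
#' @export
write_annotation_bed12 <- function(annotation, path) {
  tab <- annotation_table(annotation)
  len <- tab$end - tab$start
  bed <- data.frame(tab$chrom, tab$start, tab$end, tab$gene_id, 0L,
                    tab$strand, tab$start, tab$end, "0,0,0", 1L,
                    paste0(len, ","), "0,")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an annotation as GTF gene records
#'
#' @param annotation A `GenomeAnnotation`.
#' @param path Output file path.
#' @export
write_annotation_gtf <- function(annotation, path) {
  tab <- annotation_table(annotation)
  attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_type "%s";',
                   tab$gene_id, tab$symbol, tab$biotype)
  gtf <- data.frame(tab$chrom, "tfdirect", "gene",
                    tab$start + 1L, tab$end,  # 0-based half-open -> GTF
                    ".", tab$strand, ".", attrs)
  write.table(gtf, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Promoter windows around each TSS
#'
#' One window per gene, `[tss - flank, tss + flank)` in 0-based half-open
#' coordinates, clipped at the contig origin (never below 0). The window is
#' symmetric regardless of strand; strand only determines which gene end is
#' the TSS. Windows of different genes may overlap.
#'
#' @param annotation A `GenomeAnnotation`.
#' @param flank Half-width in bp (default 3000, the 3 kb promoter
#'   definition used for peak-to-gene assignment).
#' @return A `GRanges` of windows with mcols `gene_id`.
#' @export
promoter_windows <- function(annotation, flank = 3000L) {
  if (!is.numeric(flank) || length(flank) != 1L || flank <= 0)
    stop("flank must be a single positive number")
  flank <- as.integer(flank)
  tss0 <- mcols(annotation$genes)$tss
  win_start0 <- pmax(tss0 - flank, 0L)
  win_end0 <- tss0 + flank
  w <- GRanges(seqnames(annotation$genes),
               IRanges(win_start0 + 1L, win_end0),
               strand = "*")
  mcols(w)$gene_id <- mcols(annotation$genes)$gene_id
  w
}

#' Write promoter windows as BED6
#'
#' @param windows `GRanges` from [promoter_windows()].
#' @param path Output file path.
#' @export
write_windows_bed6 <- function(windows, path) {
  bed <- data.frame(as.character(seqnames(windows)), start(windows) - 1L,
                    end(windows), mcols(windows)$gene_id, 0L, ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Nearest TSS to a set of positions
#'
#' Indexed nearest-TSS lookup. Positions on chromosomes absent from the
#' annotation get `NA`.
#'
#' @param annotation A `GenomeAnnotation`.
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of query positions (0-based).
#' @return data.frame with `gene_id` and `distance` (signed: `pos - tss` on
#'   the `+` strand, `tss - pos` on the `-` strand, so positive values lie
#'   downstream of the TSS).
#' @export
nearest_tss <- function(annotation, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  q <- GRanges(chrom, IRanges(as.integer(pos) + 1L, width = 1L))
  tss <- annotation$tss
  hit <- suppressWarnings(GenomicRanges::nearest(q, tss, ignore.strand = TRUE))
  gene_id <- rep(NA_character_, length(q))
  dist <- rep(NA_integer_, length(q))
  ok <- !is.na(hit)
  if (any(ok)) {
    t_at <- tss[hit[ok]]
    gene_id[ok] <- mcols(t_at)$gene_id
    raw <- as.integer(pos[ok]) - (start(t_at) - 1L)
    neg <- as.character(strand(t_at)) == "-"
    dist[ok] <- ifelse(neg, -raw, raw)
  }
  data.frame(gene_id = gene_id, distance = dist, stringsAsFactors = FALSE)
}
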