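#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: two cell lines with
#' three knockdown and three control replicates each, negative-binomial
#' gene counts with planted knockdown effects, promoter or enhancer-linked
#' binding for true direct targets, a log-expression clinical cohort with
#' planted TF correlations and GCB/ABC subtype structure, and an
#' essential-gene list overlapping the positively regulated targets.
#'
#' @param seed Mandatory RNG seed; all randomness (including per-file
#'   sub-streams) derives from it.
#' @param n_genes Total genes (default 2000).
#' @param n_chroms Chromosomes to spread genes over (default 4).
#' @param n_cell_lines Cell lines (default 2).
#' @param n_replicates Replicates per condition per line (default 3).
#' @param n_direct_pos,n_direct_neg Promoter-bound true targets, positively
#'   or negatively regulated by the TF (defaults 40/40).
#' @param n_distal_pos,n_distal_neg Enhancer-only true targets (defaults
#'   10/10).
#' @param n_indirect Genes differentially expressed without any binding
#'   (default 100).
#' @param effect_size_log2 Planted |log2 fold change| (default 1.0).
#' @param nb_dispersion Negative-binomial dispersion (default 0.05,
#'   replicate-level variability of a cultured cell line; clinical cohorts
#'   run several-fold higher).
#' @param background_peak_count Peaks not tied to any planted target
#'   (default 500), split between intragenic and intergenic locations.
#' @param clinical_n_gcb,clinical_n_abc Clinical specimens per subtype
#'   (defaults 75/75).
#' @param clinical_target_r Planted TF-target Pearson correlation in the
#'   clinical cohort (default 0.6; sign follows regulation).
#' @param essential_fraction Fraction of positively regulated direct
#'   targets flagged essential (default 0.4).
#' @param flank Promoter half-width the truth is constructed against
#'   (default 3000).
#' @param peak_width ChIP peak width in bp (default 300).
#' @param motif_consensus Motif planted in true-target peak sequences
#'   (default `ACAGGAAGTG`, an ETS-core site).
#' @return A validated `SimConfig` list.
#' @export
sim_config <- function(seed,
                       n_genes = 2000L, n_chroms = 4L,
                       n_cell_lines = 2L, n_replicates = 3L,
                       n_direct_pos = 40L, n_direct_neg = 40L,
                       n_distal_pos = 10L, n_distal_neg = 10L,
                       n_indirect = 100L,
                       effect_size_log2 = 1.0,
                       nb_dispersion = 0.05,
                       background_peak_count = 500L,
                       clinical_n_gcb = 75L, clinical_n_abc = 75L,
                       clinical_target_r = 0.6,
                       essential_fraction = 0.4,
                       flank = 3000L, peak_width = 300L,
                       motif_consensus = "ACAGGAAGTG") {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_chroms = as.integer(n_chroms),
              n_cell_lines = as.integer(n_cell_lines),
              n_replicates = as.integer(n_replicates),
              n_direct_pos = as.integer(n_direct_pos),
              n_direct_neg = as.integer(n_direct_neg),
              n_distal_pos = as.integer(n_distal_pos),
              n_distal_neg = as.integer(n_distal_neg),
              n_indirect = as.integer(n_indirect),
              effect_size_log2 = effect_size_log2,
              nb_dispersion = nb_dispersion,
              background_peak_count = as.integer(background_peak_count),
              clinical_n_gcb = as.integer(clinical_n_gcb),
              clinical_n_abc = as.integer(clinical_n_abc),
              clinical_target_r = clinical_target_r,
              essential_fraction = essential_fraction,
              flank = as.integer(flank), peak_width = as.integer(peak_width),
              motif_consensus = toupper(motif_consensus))
  n_special <- with(cfg, n_direct_pos + n_direct_neg + n_distal_pos +
                      n_distal_neg + n_indirect)
  if (n_special > cfg$n_genes)
    stop("target categories exceed n_genes")
  counts <- unlist(cfg[c("n_genes", "n_chroms", "n_cell_lines",
                         "n_replicates", "n_direct_pos", "n_direct_neg",
                         "n_distal_pos", "n_distal_neg", "n_indirect",
                         "background_peak_count")])
  if (any(counts < 0)) stop("all counts must be nonnegative")
  if (cfg$n_replicates < 2) stop("need >= 2 replicates per condition")
  if (abs(cfg$clinical_target_r) >= 1) stop("|clinical_target_r| must be < 1")
  structure(cfg, class = "SimConfig")
}

# Deterministic gene layout: one 50 kb slot per gene so that promoter
# windows, enhancer anchors, intragenic and intergenic peak positions of
# different genes can never collide.
.slot_size <- 50000L

#' Plant the per-gene ground truth
#'
#' Assigns every gene a category (`direct_pos_promoter`,
#' `direct_neg_promoter`, `direct_pos_distal`, `direct_neg_distal`,
#' `indirect`, `null`), a genomic location, a planted log2 fold change, a
#' planted clinical correlation and an essentiality flag. Draws from R's
#' RNG; callers seed it (see [simulate_dataset()]).
#'
#' @param config A `SimConfig`.
#' @return data.frame, one row per gene (plus all layout columns used by
#'   the emitters).
#' @export
simulate_truth <- function(config) {
  n <- config$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))
  chrom <- paste0("chr", rep_len(seq_len(config$n_chroms), n))
  slot <- integer(n)
  for (cc in unique(chrom)) {
    i <- which(chrom == cc)
    slot[i] <- (seq_along(i) - 1L) * .slot_size
  }
  gene_len <- as.integer(round(runif(n, 10000, 16000)))
  start <- slot + 20000L
  end <- start + gene_len
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- ifelse(strand == "+", start, end - 1L)

  cat_levels <- c("direct_pos_promoter", "direct_neg_promoter",
                  "direct_pos_distal", "direct_neg_distal",
                  "indirect", "null")
  category <- rep("null", n)
  pool <- sample(n)
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  category[take(config$n_direct_pos)] <- "direct_pos_promoter"
  category[take(config$n_direct_neg)] <- "direct_neg_promoter"
  category[take(config$n_distal_pos)] <- "direct_pos_distal"
  category[take(config$n_distal_neg)] <- "direct_neg_distal"
  category[take(config$n_indirect)] <- "indirect"
  category <- factor(category, levels = cat_levels)

  # positive regulation by the TF => expression drops on knockdown
  regulation <- ifelse(grepl("pos", category), "positive",
                       ifelse(grepl("neg", category), "negative", "none"))
  indirect_sign <- sample(c(-1, 1), n, replace = TRUE)
  planted_lfc <- ifelse(regulation == "positive", -config$effect_size_log2,
                        ifelse(regulation == "negative",
                               config$effect_size_log2, 0))
  planted_lfc[category == "indirect"] <-
    indirect_sign[category == "indirect"] * config$effect_size_log2

  direct <- grepl("^direct", category)
  planted_r <- ifelse(direct & regulation == "positive",
                      config$clinical_target_r,
                      ifelse(direct & regulation == "negative",
                             -config$clinical_target_r, 0))

  essential <- rep(FALSE, n)
  pos_direct <- which(direct & regulation == "positive")
  if (length(pos_direct) > 0 && config$essential_fraction > 0) {
    k <- max(1L, round(config$essential_fraction * length(pos_direct)))
    essential[sample(pos_direct, min(k, length(pos_direct)))] <- TRUE
  }
  null_idx <- which(category == "null")
  if (length(null_idx) > 20)
    essential[sample(null_idx, round(0.05 * length(null_idx)))] <- TRUE

  # expressed baseline; direct/indirect targets are expressed genes (a
  # knockdown-responsive target must be detectable), so their baseline is
  # floored well above the CPM filter
  base_mean <- rlnorm(n, meanlog = log(300), sdlog = 1.2)
  base_mean[category != "null"] <- pmax(base_mean[category != "null"], 30)

  data.frame(gene_id = gene_id, chrom = chrom, slot = slot,
             start = start, end = end, strand = strand, tss = tss,
             category = as.character(category), regulation = regulation,
             planted_lfc = planted_lfc, planted_r = planted_r,
             essential = essential, base_mean = base_mean,
             stringsAsFactors = FALSE)
}

#' Simulate knockdown count data
#'
#' Negative-binomial counts, genes x (cell lines x conditions x
#' replicates). Baselines are drawn log-normally (in [simulate_truth()]),
#' modulated per cell line, and knockdown samples of planted targets are
#' scaled by `2^planted_lfc`; library sizes are jittered by +/-20%.
#'
#' @param truth Truth table from [simulate_truth()].
#' @param config A `SimConfig`.
#' @return list with `counts` (integer matrix) and `samples` (data.frame).
#' @export
simulate_counts <- function(truth, config) {
  lines <- paste0("line", seq_len(config$n_cell_lines))
  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         condition = c("control", "knockdown"),
                         cell_line = lines, stringsAsFactors = FALSE)
  samples <- samples[, c("cell_line", "condition", "replicate")]
  samples$sample <- with(samples, paste(cell_line, condition, replicate,
                                        sep = "_"))
  n <- nrow(truth); m <- nrow(samples)
  line_effect <- matrix(2^rnorm(n * config$n_cell_lines, 0, 0.2), nrow = n,
                        dimnames = list(NULL, lines))
  line_effect[, 1] <- 1
  lib_factor <- runif(m, 0.8, 1.2)
  size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
  counts <- matrix(0L, n, m, dimnames = list(truth$gene_id, samples$sample))
  for (j in seq_len(m)) {
    mu <- truth$base_mean * line_effect[, samples$cell_line[j]] * lib_factor[j]
    if (samples$condition[j] == "knockdown")
      mu <- mu * 2^truth$planted_lfc
    counts[, j] <- if (is.finite(size))
      rnbinom(n, mu = mu, size = size)
    else rpois(n, mu)
  }
  storage.mode(counts) <- "integer"
  list(counts = counts, samples = samples)
}

#' Simulate a clinical expression cohort
#'
#' Log-scale expression for all genes plus a TF row (`TF1`). The TF is
#' normal with a higher mean in GCB than ABC specimens (so the median
#' dichotomization has planted subtype signal); each direct target is drawn
#' jointly with the TF at its planted correlation (sign following
#' regulation); all other genes are independent.
#'
#' @param truth Truth table from [simulate_truth()].
#' @param config A `SimConfig`.
#' @return list with `expr` (matrix, `TF1` first row) and `samples`
#'   (data.frame with `sample`, `subtype`).
#' @export
simulate_clinical_matrix <- function(truth, config) {
  n_g <- config$clinical_n_gcb; n_a <- config$clinical_n_abc
  m <- n_g + n_a
  subtype <- c(rep("GCB", n_g), rep("ABC", n_a))
  sample_id <- sprintf("S%04d", seq_len(m))
  tf <- rnorm(m, mean = ifelse(subtype == "GCB", 1, 0), sd = 1)
  z <- (tf - mean(tf)) / sd(tf)
  expr <- matrix(NA_real_, nrow(truth) + 1L, m,
                 dimnames = list(c("TF1", truth$gene_id), sample_id))
  expr["TF1", ] <- tf
  r <- truth$planted_r
  noise <- matrix(rnorm(nrow(truth) * m), nrow(truth), m)
  expr[-1, ] <- r * matrix(z, nrow(truth), m, byrow = TRUE) +
    sqrt(1 - r^2) * noise + 5  # arbitrary log-expression offset
  list(expr = expr,
       samples = data.frame(sample = sample_id, subtype = subtype,
                            stringsAsFactors = FALSE))
}

.random_dna <- function(n_bases) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE), collapse = "")
}

#' Generate the full synthetic data bundle
#'
#' Writes an internally consistent dataset to `outdir`: gene annotation
#' (GTF and BED12), per-cell-line peak BEDs, the knockdown count matrix and
#' sample sheet, the enhancer-promoter interaction map, the clinical
#' expression matrix and subtype sheet, the essential-gene list, peak
#' sequences (FASTA, with the consensus motif planted in true-target
#' peaks), and the machine-readable ground truth. Deterministic given the
#' seed: per-stage sub-seeds are derived from `config$seed`.
#'
#' Construction invariants: every promoter-category target has at least one
#' peak overlapping its promoter window in at least one cell line; every
#' distal-category target has an enhancer-linked peak farther than `flank`
#' from every TSS and no peak in its own promoter; indirect genes have no
#' binding at all; background peaks avoid all promoter windows and all
#' enhancer anchors.
#'
#' @param config A `SimConfig`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with all in-memory objects (`truth`,
#'   `annotation`, `peaks`, `counts`, `clinical`, `interactions`,
#'   `essential`, `sequences`) and `files` (named paths).
#' @export
simulate_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "SimConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)

  set.seed(config$seed)
  truth <- simulate_truth(config)
  lines <- paste0("line", seq_len(config$n_cell_lines))

  ## ChIP peaks -------------------------------------------------------------
  peak_rows <- list()
  add_peak <- function(chrom, start0, kind, gene, in_lines) {
    peak_rows[[length(peak_rows) + 1]] <<- data.frame(
      chrom = chrom, start = start0, end = start0 + config$peak_width,
      kind = kind, gene = gene, lines = paste(in_lines, collapse = ","),
      stringsAsFactors = FALSE)
  }
  pick_lines <- function() {
    k <- sample(seq_len(config$n_cell_lines), 1)
    sample(lines, k)
  }
  for (i in which(grepl("promoter$", truth$category))) {
    offset <- round(runif(1, -(config$flank - config$peak_width - 100),
                          config$flank - config$peak_width - 100))
    add_peak(truth$chrom[i], truth$tss[i] + offset, "promoter",
             truth$gene_id[i], pick_lines())
  }
  # distal targets: enhancer anchor near the start of the gene's slot,
  # > flank away from every TSS by layout
  distal_idx <- which(grepl("distal$", truth$category))
  for (i in distal_idx) {
    add_peak(truth$chrom[i], truth$slot[i] + 2500L, "enhancer",
             truth$gene_id[i], pick_lines())
  }
  null_idx <- which(truth$category == "null")
  n_bg <- config$background_peak_count
  if (n_bg > 0) {
    bg_gene <- sample(null_idx, n_bg, replace = TRUE)
    bg_kind <- sample(c("intragenic_bg", "intergenic_bg"), n_bg,
                      replace = TRUE)
    for (j in seq_len(n_bg)) {
      i <- bg_gene[j]
      start0 <- if (bg_kind[j] == "intragenic_bg")
        truth$start[i] + 4500L else truth$slot[i] + 40000L
      start0 <- start0 + sample.int(500L, 1)
      add_peak(truth$chrom[i], start0, bg_kind[j], NA_character_, pick_lines())
    }
  }
  peak_tab <- do.call(rbind, peak_rows)
  peak_tab$name <- sprintf("peak_%04d", seq_len(nrow(peak_tab)))
  peak_tab$score <- round(runif(nrow(peak_tab), 20, 200), 2)

  ## interaction map: true enhancer pairs + decoys on null genes -----------
  enh <- truth[distal_idx, , drop = FALSE]
  pairs <- data.frame(
    chrom1 = enh$chrom, start1 = enh$slot + 2000L, end1 = enh$slot + 4000L,
    chrom2 = enh$chrom, start2 = pmax(enh$tss - 1000L, 0L),
    end2 = enh$tss + 1000L, genes = enh$gene_id, stringsAsFactors = FALSE)
  n_decoy <- min(100L, length(null_idx))
  if (n_decoy > 0) {
    dec <- truth[sample(null_idx, n_decoy), , drop = FALSE]
    pairs <- rbind(pairs, data.frame(
      chrom1 = dec$chrom, start1 = dec$slot + 10000L,
      end1 = dec$slot + 12000L, chrom2 = dec$chrom,
      start2 = pmax(dec$tss - 1000L, 0L), end2 = dec$tss + 1000L,
      genes = dec$gene_id, stringsAsFactors = FALSE))
  }

  ## counts, clinical, essential -------------------------------------------
  set.seed((config$seed + 1001L) %% .Machine$integer.max)
  cm <- simulate_counts(truth, config)
  set.seed((config$seed + 2002L) %% .Machine$integer.max)
  clin <- simulate_clinical_matrix(truth, config)
  essential <- truth$gene_id[truth$essential]

  ## peak sequences with planted motif -------------------------------------
  set.seed((config$seed + 3003L) %% .Machine$integer.max)
  motif <- config$motif_consensus
  seqs <- vapply(seq_len(nrow(peak_tab)), function(j) {
    s <- .random_dna(config$peak_width)
    if (peak_tab$kind[j] %in% c("promoter", "enhancer")) {
      at <- sample.int(config$peak_width - nchar(motif) + 1L, 1)
      substr(s, at, at + nchar(motif) - 1L) <- motif
    }
    s
  }, "")
  names(seqs) <- peak_tab$name

  ## emit files -------------------------------------------------------------
  annotation <- genome_annotation(truth[, c("gene_id", "chrom", "start",
                                            "end", "strand")])
  fp <- function(x) file.path(outdir, x)
  files <- c(annotation_gtf = fp("annotation.gtf"),
             annotation_bed12 = fp("annotation.bed12"),
             counts = fp("counts.tsv"), samples = fp("samples.tsv"),
             interactions = fp("interactions.tsv"),
             clinical = fp("clinical_expression.tsv"),
             clinical_samples = fp("clinical_samples.tsv"),
             essential = fp("essential_genes.tsv"),
             fasta = fp("peak_sequences.fa"),
             truth = fp("truth.tsv"))
  write_annotation_gtf(annotation, files["annotation_gtf"])
  write_annotation_bed12(annotation, files["annotation_bed12"])
  for (ln in lines) {
    sel <- vapply(strsplit(peak_tab$lines, ","), function(x) ln %in% x, TRUE)
    bed <- peak_tab[sel, c("chrom", "start", "end", "name", "score")]
    write.table(bed, fp(paste0("peaks_", ln, ".bed")), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    files[paste0("peaks_", ln)] <- fp(paste0("peaks_", ln, ".bed"))
  }
  counts_out <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                           check.names = FALSE)
  write.table(counts_out, files["counts"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cm$samples, files["samples"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(pairs, files["interactions"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  clin_out <- data.frame(gene_id = rownames(clin$expr),
                         round(clin$expr, 6), check.names = FALSE)
  write.table(clin_out, files["clinical"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(clin$samples, files["clinical_samples"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = essential), files["essential"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste0(">", names(seqs), "\n", seqs), files["fasta"])
  truth_out <- truth[, c("gene_id", "chrom", "start", "end", "strand",
                         "tss", "category", "regulation", "planted_lfc",
                         "planted_r", "essential")]
  write.table(truth_out, files["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)

  invisible(list(truth = truth, annotation = annotation,
                 peaks = peak_tab, counts = cm, clinical = clin,
                 interactions = pairs, essential = essential,
                 sequences = seqs, files = files, config = config))
}

#' Validate a synthetic bundle against its ground truth
#'
#' Re-reads the emitted files and asserts the generator's construction
#' invariants: promoter-category targets have a peak in their promoter
#' window, distal-category targets have an enhancer-linked distal peak and
#' a peak-free promoter, indirect genes are peak-free, and the annotation
#' round-trips.
#'
#' @param outdir Directory written by [simulate_dataset()].
#' @param flank Promoter half-width used at generation (default 3000).
#' @return TRUE invisibly; stops on any violation.
#' @export
validate_bundle <- function(outdir, flank = 3000L) {
  truth <- read.delim(file.path(outdir, "truth.tsv"),
                      stringsAsFactors = FALSE)
  ann <- read_gene_annotation(file.path(outdir, "annotation.gtf"), "gtf")
  win <- promoter_windows(ann, flank)
  peak_files <- list.files(outdir, "^peaks_.*\\.bed$", full.names = TRUE)
  annotated <- lapply(peak_files, function(f) {
    ln <- sub("^peaks_(.*)\\.bed$", "\\1", basename(f))
    annotate_peaks(read_peaks(f, ln), ann, win)
  })
  sets <- promoter_gene_sets(setNames(annotated,
                                      vapply(annotated, function(a)
                                        mcols(a)$cell_line[1], "")))
  prom_true <- truth$gene_id[grepl("promoter$", truth$category)]
  if (!all(prom_true %in% sets$union))
    stop("promoter-category target without a promoter peak")
  distal_true <- truth$gene_id[grepl("distal$", truth$category)]
  if (any(distal_true %in% sets$union))
    stop("distal-category target has a promoter peak")
  imap <- read_interaction_map(file.path(outdir, "interactions.tsv"))
  pooled <- do.call(c, annotated)
  linked <- link_distal_peaks(pooled, imap, flank)
  if (!all(distal_true %in% names(linked)))
    stop("distal-category target without an enhancer-linked peak")
  indirect <- truth$gene_id[truth$category == "indirect"]
  if (any(indirect %in% sets$union) || any(indirect %in% names(linked)))
    stop("indirect gene has binding evidence")
  ann2 <- read_gene_annotation(file.path(outdir, "annotation.bed12"), "bed12")
  t1 <- annotation_table(ann)[, c("gene_id", "chrom", "start", "end",
                                  "strand", "tss")]
  t2 <- annotation_table(ann2)[, c("gene_id", "chrom", "start", "end",
                                   "strand", "tss")]
  if (!identical(t1[order(t1$gene_id), ], t2[order(t2$gene_id), ]))
    stop("annotation GTF/BED12 round-trip mismatch")
  invisible(TRUE)
}
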