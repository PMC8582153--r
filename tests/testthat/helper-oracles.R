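# Independent brute-force oracles and small fixture builders.
# Everything here is deliberately written as plain double loops over
# 0-based half-open intervals, sharing no code with the package internals.

# random gene table (0-based half-open coordinates) spread over chromosomes
random_gene_table <- function(n, n_chroms = 2, span = 1e6) {
  start <- sort(sample.int(span - 20000L, n))
  len <- sample(500:8000, n, replace = TRUE)
  data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = sample(paste0("chr", seq_len(n_chroms)), n, replace = TRUE),
    start = start,
    end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

random_peak_table <- function(n, n_chroms = 2, span = 1e6) {
  start <- sample.int(span, n)
  data.frame(
    chrom = sample(paste0("chr", seq_len(n_chroms)), n, replace = TRUE),
    start = start,
    end = start + sample(50:1000, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

peaks_granges <- function(df, cell_line = "lineX") {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  S4Vectors::mcols(gr)$cell_line <- cell_line
  S4Vectors::mcols(gr)$name <- paste0("pk", seq_len(nrow(df)))
  S4Vectors::mcols(gr)$score <- 1
  gr
}

# half-open interval overlap
.hop <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# exhaustive O(P x G) peak annotation: context, promoter gene set,
# absolute nearest-TSS distance from the peak midpoint
oracle_annotate <- function(peaks, genes, flank = 3000) {
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  win_s <- pmax(tss - flank, 0L)
  win_e <- tss + flank
  out <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    same <- genes$chrom == peaks$chrom[i]
    prom <- same & .hop(peaks$start[i], peaks$end[i], win_s, win_e)
    body <- same & .hop(peaks$start[i], peaks$end[i], genes$start, genes$end)
    ctx <- if (any(prom)) "promoter" else if (any(body)) "intragenic"
    else "intergenic"
    mid <- (peaks$start[i] + peaks$end[i]) %/% 2
    absdist <- if (any(same)) min(abs(mid - tss[same])) else NA_integer_
    out[[i]] <- list(context = ctx,
                     promoter_genes = sort(genes$gene_id[prom]),
                     abs_distance = absdist)
  }
  out
}

# exhaustive double loop: distal peaks (|abs distance| > flank) through
# enhancer anchors to gene sets
oracle_link <- function(peaks, abs_dist, anchors, flank = 3000) {
  res <- list()
  for (i in seq_len(nrow(peaks))) {
    if (!is.na(abs_dist[i]) && abs_dist[i] <= flank) next
    for (j in seq_len(nrow(anchors))) {
      if (peaks$chrom[i] != anchors$chrom1[j]) next
      if (.hop(peaks$start[i], peaks$end[i],
               anchors$start1[j], anchors$end1[j])) {
        for (g in strsplit(anchors$genes[j], ",")[[1]])
          res[[g]] <- sort(unique(c(res[[g]], paste0("pk", i))))
      }
    }
  }
  res[sort(names(res))]
}

# per-gene OLS t for the knockdown coefficient, via lm() gene by gene
oracle_ols_t <- function(logexpr, samples) {
  cond <- factor(samples$condition, levels = c("control", "knockdown"))
  line <- factor(samples$cell_line)
  multi <- nlevels(line) > 1
  t(vapply(seq_len(nrow(logexpr)), function(g) {
    y <- logexpr[g, ]
    fit <- if (multi) lm(y ~ cond + line) else lm(y ~ cond)
    s <- summary(fit)$coefficients
    c(logFC = s[2, 1], t = s[2, 3], p = s[2, 4])
  }, c(logFC = 0, t = 0, p = 0)))
}

# naive window scorer used as the motif-scan oracle
oracle_scan <- function(seq, lo, threshold) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  W <- ncol(lo)
  score1 <- function(s, off) {
    w <- strsplit(substr(s, off, off + W - 1), "")[[1]]
    if (any(!w %in% c("A", "C", "G", "T"))) return(NA_real_)
    sum(lo[cbind(match(w, c("A", "C", "G", "T")), seq_len(W))])
  }
  L <- nchar(seq)
  rows <- list()
  if (L >= W) {
    rc <- paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
    for (off in 1:(L - W + 1)) {
      sf <- score1(seq, off)
      if (!is.na(sf) && sf >= threshold)
        rows[[length(rows) + 1]] <- data.frame(offset = off - 1L,
                                               strand = "+", score = sf)
      sr <- score1(rc, off)
      if (!is.na(sr) && sr >= threshold)
        rows[[length(rows) + 1]] <- data.frame(offset = L - W + 1L - off,
                                               strand = "-", score = sr)
    }
  }
  if (length(rows) == 0)
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$strand, out$offset), , drop = FALSE]
}

dinuc_counts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# minimal pipeline config for a simulated bundle directory
bundle_config <- function(d, seed = 1, lines = c("line1", "line2")) {
  pk <- as.list(file.path(d, paste0("peaks_", lines, ".bed")))
  names(pk) <- lines
  list(
    annotation = file.path(d, "annotation.gtf"),
    peaks = pk,
    counts = file.path(d, "counts.tsv"),
    samples = file.path(d, "samples.tsv"),
    interactions = file.path(d, "interactions.tsv"),
    clinical = file.path(d, "clinical_expression.tsv"),
    clinical_samples = file.path(d, "clinical_samples.tsv"),
    essential = file.path(d, "essential_genes.tsv"),
    tf_gene = "TF1",
    seed = seed
  )
}
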