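test_that("BED3+ peak parsing validates records and ignores optional columns", {
  f3 <- tempfile(); writeLines(c("chr1\t100\t200", "chr2\t5\t50"), f3)
  p3 <- read_peaks(f3, "L1")
  expect_equal(GenomicRanges::start(p3) - 1L, c(100, 5))
  expect_equal(GenomicRanges::end(p3), c(200, 50))
  expect_equal(unique(S4Vectors::mcols(p3)$cell_line), "L1")

  f5 <- tempfile()
  writeLines(c("chr1\t100\t200\tpkA\t7.5", "chr2\t5\t50\tpkB\t1"), f5)
  p5 <- read_peaks(f5, "L1")
  expect_equal(GenomicRanges::ranges(p5), GenomicRanges::ranges(p3))
  expect_equal(S4Vectors::mcols(p5)$score, c(7.5, 1))

  inv <- tempfile(); writeLines("chr1\t200\t100", inv)
  expect_error(read_peaks(inv, "L1"), "start >= end")
  bad <- tempfile(); writeLines("chr1\tx\t100", bad)
  expect_error(read_peaks(bad, "L1"), "non-numeric")
})

test_that("context precedence and promoter assignment follow the window overlap rule", {
  df <- data.frame(gene_id = "G", chrom = "chr1", start = 50000,
                   end = 60000, strand = "+")
  ann <- genome_annotation(df)
  win <- promoter_windows(ann, 3000)
  pk <- peaks_granges(data.frame(chrom = "chr1",
                                 start = c(49900, 55000, 100000),
                                 end = c(50100, 55200, 100300)))
  a <- annotate_peaks(pk, ann, win)
  expect_equal(S4Vectors::mcols(a)$context,
               c("promoter", "intragenic", "intergenic"))
  expect_true("G" %in% S4Vectors::mcols(a)$promoter_genes[[1]])
  # isolated peak: midpoint 100150, TSS 50000
  expect_equal(abs(S4Vectors::mcols(a)$tss_distance[3]), 50150)
  # unknown chromosome -> intergenic with warning, NA nearest fields
  pkz <- peaks_granges(data.frame(chrom = "chrZ", start = 1, end = 100))
  expect_warning(az <- annotate_peaks(pkz, ann, win), "absent")
  expect_equal(S4Vectors::mcols(az)$context, "intergenic")
  expect_true(is.na(S4Vectors::mcols(az)$nearest_gene))
})

test_that("annotation matches the exhaustive scan and is order-invariant", {
  set.seed(21)
  genes <- random_gene_table(60, n_chroms = 2)
  peaks <- random_peak_table(300, n_chroms = 2)
  ann <- genome_annotation(genes)
  win <- promoter_windows(ann, 3000)
  a <- annotate_peaks(peaks_granges(peaks), ann, win)
  oracle <- oracle_annotate(peaks, genes, 3000)
  for (i in seq_len(nrow(peaks))) {
    expect_equal(S4Vectors::mcols(a)$context[i], oracle[[i]]$context)
    expect_equal(S4Vectors::mcols(a)$promoter_genes[[i]],
                 oracle[[i]]$promoter_genes)
    expect_equal(abs(S4Vectors::mcols(a)$tss_distance[i]),
                 oracle[[i]]$abs_distance)
  }
  # context partition is exhaustive/exclusive
  expect_equal(sum(table(S4Vectors::mcols(a)$context)), nrow(peaks))
  # permuting the peak input permutes the output identically
  perm <- sample(nrow(peaks))
  a2 <- annotate_peaks(peaks_granges(peaks[perm, ]), ann, win)
  expect_equal(S4Vectors::mcols(a2)$context,
               S4Vectors::mcols(a)$context[perm])
})

test_that("promoter gene sets obey set algebra and the generator ground truth", {
  mk <- function(genes) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2))
    gr <- rep(gr, length(genes))
    S4Vectors::mcols(gr)$promoter_genes <-
      IRanges::CharacterList(as.list(genes))
    gr
  }
  s <- promoter_gene_sets(list(A = mk(c("g1", "g2")), B = mk(c("g2", "g3"))))
  expect_equal(s$union, c("g1", "g2", "g3"))
  expect_equal(s$common, "g2")
  single <- promoter_gene_sets(list(A = mk(c("g1", "g2"))))
  expect_equal(single$union, single$common)
  expect_error(promoter_gene_sets(list()), "cell line")

  sim <- simulate_dataset(sim_config(seed = 301, n_genes = 300,
                                     n_direct_pos = 15, n_direct_neg = 15,
                                     n_distal_pos = 4, n_distal_neg = 4,
                                     n_indirect = 10,
                                     background_peak_count = 60),
                          tempfile("bundle"))
  ann <- genome_annotation(sim$truth[, c("gene_id", "chrom", "start",
                                         "end", "strand")])
  win <- promoter_windows(ann, 3000)
  annotated <- lapply(c(line1 = "line1", line2 = "line2"), function(ln)
    annotate_peaks(read_peaks(sim$files[[paste0("peaks_", ln)]], ln),
                   ann, win))
  sets <- promoter_gene_sets(annotated)
  planted <- sort(sim$truth$gene_id[grepl("promoter$", sim$truth$category)])
  expect_equal(sets$union, planted)
})

test_that("context distribution is a normalized partition", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:4, 5:8))
  S4Vectors::mcols(gr)$context <- c("promoter", "promoter", "promoter",
                                    "promoter")
  d <- context_distribution(gr)
  expect_equal(unname(d), c(1, 0, 0))
  S4Vectors::mcols(gr)$context <- c("promoter", "intragenic", "intergenic",
                                    "intergenic")
  expect_equal(sum(context_distribution(gr)), 1, tolerance = 1e-9)
  expect_error(context_distribution(gr[0]), "no annotated peaks")
})
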