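small_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_genes = 300, n_direct_pos = 15,
             n_direct_neg = 15, n_distal_pos = 4, n_distal_neg = 4,
             n_indirect = 10, background_peak_count = 60, ...)
}

test_that("the generator is deterministic and byte-identical given a seed", {
  d1 <- tempfile("sim1"); d2 <- tempfile("sim2")
  simulate_dataset(small_cfg(91), d1)
  simulate_dataset(small_cfg(91), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the data
  d3 <- tempfile("sim3")
  simulate_dataset(small_cfg(92), d3)
  expect_false(identical(readLines(file.path(d1, "counts.tsv")),
                         readLines(file.path(d3, "counts.tsv"))))
})

test_that("the emitted bundle satisfies every ground-truth invariant", {
  d <- tempfile("simv")
  simulate_dataset(small_cfg(93), d)
  expect_true(validate_bundle(d))
})

test_that("config validation rejects inconsistent requests", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(seed = 1, n_genes = 10, n_direct_pos = 20),
               "exceed")
  expect_error(sim_config(seed = 1, n_replicates = 1), "replicates")
  expect_error(sim_config(seed = 1, clinical_target_r = 1), "clinical_target_r")
})

test_that("planted count effects have the requested size and direction", {
  cfg <- small_cfg(94)
  set.seed(94)
  truth <- simulate_truth(cfg)
  cm <- simulate_counts(truth, cfg)
  ft <- filter_and_transform(cm$counts)
  de <- moderated_t_test(ft$logcpm, cm$samples)$table
  m <- merge(de, truth[, c("gene_id", "planted_lfc", "category")],
             by = "gene_id")
  pos <- m$planted_lfc < 0
  expect_equal(mean(m$logFC[pos]), -cfg$effect_size_log2, tolerance = 0.2)
  # null genes' realized logFC is centered at zero
  expect_lt(abs(mean(m$logFC[m$category == "null"])), 0.1)
  # effect size 0 removes the condition effect entirely
  cfg0 <- small_cfg(94, effect_size_log2 = 0)
  set.seed(94)
  truth0 <- simulate_truth(cfg0)
  expect_true(all(truth0$planted_lfc == 0))
  cm0 <- simulate_counts(truth0, cfg0)
  kd <- cm0$samples$condition == "knockdown"
  # compare on the library-size-normalized scale (library jitter is real)
  cpm0 <- sweep(cm0$counts, 2, colSums(cm0$counts), "/") * 1e6
  expect_equal(mean(cpm0[, kd]) / mean(cpm0[, !kd]), 1, tolerance = 0.02)
})

test_that("zero dispersion degrades to Poisson-like variance", {
  cfg <- small_cfg(95, nb_dispersion = 0)
  set.seed(95)
  truth <- simulate_truth(cfg)
  truth$base_mean <- rep(100, nrow(truth))  # common mean isolates the check
  truth$planted_lfc <- 0
  cm <- simulate_counts(truth, cfg)
  # restrict to the reference cell line, whose per-gene modulation factor
  # is 1: within one of its columns all genes share the same mean, so the
  # across-gene variance/mean ratio is the Poisson index
  ref_cols <- cm$samples$cell_line == "line1"
  ratio <- apply(cm$counts[, ref_cols], 2, var) /
    colMeans(cm$counts[, ref_cols])
  expect_true(all(ratio > 0.7 & ratio < 1.4))
})

test_that("the clinical cohort carries the planted correlations and subtype shift", {
  cfg <- small_cfg(96, clinical_target_r = 0.99)
  set.seed(96)
  truth <- simulate_truth(cfg)
  clin <- simulate_clinical_matrix(truth, cfg)
  tf <- clin$expr["TF1", ]
  direct <- truth$gene_id[grepl("^direct", truth$category)]
  r_emp <- vapply(direct, function(g) cor(clin$expr[g, ], tf), 0)
  expect_true(all(abs(r_emp) > 0.9))
  signs <- sign(truth$planted_r[match(direct, truth$gene_id)])
  expect_equal(sign(r_emp), signs, ignore_attr = TRUE)
  # null genes are approximately uncorrelated
  nulls <- truth$gene_id[truth$category == "null"]
  r_null <- vapply(nulls, function(g) cor(clin$expr[g, ], tf), 0)
  expect_lt(mean(abs(r_null) > 0.3), 0.05)
  # the GCB/ABC shift makes the dichotomization test fire
  res <- dichotomize_and_test(clin$expr, "TF1", clin$samples$subtype)
  expect_lt(res$p, 0.05)
})

test_that("equal subtype means keep the dichotomization test at its nominal level", {
  set.seed(97)
  rej <- replicate(300, {
    cfg <- small_cfg(1)
    m <- cfg$clinical_n_gcb + cfg$clinical_n_abc
    tf <- rnorm(m)  # no subtype shift
    expr <- matrix(tf, 1, dimnames = list("TF1", sprintf("s%03d", 1:m)))
    dichotomize_and_test(expr, "TF1",
                         rep(c("GCB", "ABC"),
                             c(cfg$clinical_n_gcb, cfg$clinical_n_abc)))$p < 0.05
  })
  expect_lte(mean(rej), 0.07)
})
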