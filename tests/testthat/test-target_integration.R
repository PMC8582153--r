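de_row <- function(id, lfc, adj, call) {
  data.frame(gene_id = id, logFC = lfc, adj_p = adj, call = call,
             stringsAsFactors = FALSE)
}

test_that("direct-target calls gate on binding and map the knockdown sign", {
  de <- rbind(de_row("a", -1, 1e-5, "down"),   # bound + down -> positive
              de_row("b", 1.2, 1e-4, "up"),    # bound + up -> negative
              de_row("c", -2, 1e-6, "down"),   # distal only
              de_row("d", 0.0, 0.9, "ns"),     # bound but ns
              de_row("e", 3, 1e-8, "up"))      # DE without binding
  t <- call_direct_targets(de, promoter_gene_union = c("a", "b", "d"),
                           distal_only_genes = "c")
  expect_equal(t$binding, c("promoter", "promoter", "distal_only",
                            "promoter", "none"))
  expect_equal(t$regulation[t$gene_id == "a"], "positive")
  expect_equal(t$regulation[t$gene_id == "b"], "negative")
  expect_equal(t$direct, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_error(call_direct_targets(de, c("a", "c"), "c"), "disjoint")
})

test_that("clinical support requires significance plus sign concordance", {
  de <- rbind(de_row("a", -1, 1e-5, "down"), de_row("b", -1, 1e-5, "down"),
              de_row("c", 1, 1e-5, "up"))
  t <- call_direct_targets(de, c("a", "b", "c"))
  corr <- data.frame(gene_id = c("a", "b", "c"),
                     r = c(0.5, -0.5, -0.4),
                     p = c(0.001, 0.001, 0.001), sign = c("+", "-", "-"))
  out <- tier_targets(t, corr)
  expect_true(out$clinical_support[out$gene_id == "a"])   # pos reg, r > 0
  expect_false(out$clinical_support[out$gene_id == "b"])  # discordant
  expect_true(out$clinical_support[out$gene_id == "c"])   # neg reg, r < 0
  # with concordance disabled, significance alone suffices
  out2 <- tier_targets(t, corr, require_concordance = FALSE)
  expect_true(all(out2$clinical_support))
})

test_that("tier counts reproduce a hand-enumerated truth table", {
  ids <- sprintf("g%02d", 1:10)
  de <- do.call(rbind, lapply(1:10, function(i)
    de_row(ids[i], c(-1, 1)[1 + i %% 2],
           ifelse(i <= 8, 1e-4, 0.5),
           ifelse(i <= 8, c("down", "up")[1 + i %% 2], "ns"))))
  prom <- ids[1:6]; distal <- ids[7:8]
  corr <- data.frame(gene_id = ids[c(1, 2, 3)],
                     r = c(-0.5, 0.5, -0.5),  # g01 up/neg, g02 down/pos...
                     p = 1e-3, sign = c("-", "+", "-"))
  ess <- ids[c(2, 3, 9)]
  out <- tier_targets(call_direct_targets(de, prom, distal), corr, ess)
  # hand enumeration: g01..g08 direct; g01 (neg, r<0) clinical; g02 (pos,
  # r>0) clinical+essential; g03 (neg, r<0) clinical+essential
  expect_equal(out$tier[match(ids, out$gene_id)],
               c(2L, 3L, 3L, 1L, 1L, 1L, 1L, 1L, 0L, 0L))
  s <- summarize_targets(out)
  expect_equal(s$direct$positive, 4L)
  expect_equal(s$direct$negative, 4L)
  expect_equal(s$clinical_confirmed$positive, 1L)
  expect_equal(s$clinical_confirmed$negative, 2L)
  expect_equal(s$essential_overlap$positive, 1L)
  expect_equal(s$essential_overlap$negative, 1L)
  # Venn identity: every reported count equals the recomputed intersection
  expect_equal(s$direct_promoter$positive +
                 s$direct_distal$positive, s$direct$positive)
})

test_that("the pipeline validates its configuration before any compute", {
  d <- tempfile("cfg")
  dir.create(d)
  cfg <- list(annotation = file.path(d, "nope.gtf"),
              peaks = list(l1 = file.path(d, "nope.bed")),
              counts = file.path(d, "nope.tsv"),
              samples = file.path(d, "nope2.tsv"))
  expect_error(run_pipeline(cfg, file.path(d, "out")), "not found")
  expect_error(run_pipeline(list(annotation = "x"), file.path(d, "out")),
               "missing entries")
  cfg$distal <- TRUE
  expect_error(run_pipeline(cfg, file.path(d, "out")),
               "no interaction map")
})

test_that("an end-to-end run recovers the planted targets and is deterministic", {
  cfg <- sim_config(seed = 61, n_genes = 400, n_direct_pos = 20,
                    n_direct_neg = 20, n_distal_pos = 5, n_distal_neg = 5,
                    n_indirect = 20, background_peak_count = 80)
  d1 <- tempfile("run1"); d2 <- tempfile("run2")
  sim <- simulate_dataset(cfg, d1)
  res <- run_pipeline(bundle_config(d1, seed = 61), file.path(d1, "out"))
  tr <- sim$truth

  called <- res$targets[res$targets$direct, ]
  truth_direct <- tr[grepl("^direct", tr$category), ]
  hits <- merge(called, truth_direct, by = "gene_id")
  # direction concordance on every recovered target
  expect_true(all(hits$regulation.x == hits$regulation.y))
  expect_gte(nrow(hits) / nrow(called), 0.9)           # precision
  expect_gte(nrow(hits) / nrow(truth_direct), 0.8)     # recall at small n
  # indirect genes are never called direct (binding gate)
  expect_length(intersect(called$gene_id,
                          tr$gene_id[tr$category == "indirect"]), 0)
  # distal-only output contains no promoter-bound gene
  expect_length(intersect(res$distal_only, res$promoter_sets$union), 0)
  # summary counts satisfy the recomputed set identities
  s <- res$summary
  expect_equal(s$direct$positive,
               sum(called$regulation == "positive"))
  expect_equal(s$direct_promoter$negative + s$direct_distal$negative,
               s$direct$negative)

  # same seed -> byte-identical truth and summary
  simulate_dataset(cfg, d2)
  run_pipeline(bundle_config(d2, seed = 61), file.path(d2, "out"))
  for (f in c("truth.tsv", file.path("out", "summary.json"),
              file.path("out", "targets.tsv")))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})
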