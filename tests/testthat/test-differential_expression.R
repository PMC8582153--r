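make_samples <- function(n_lines = 2, reps = 3) {
  s <- expand.grid(replicate = seq_len(reps),
                   condition = c("control", "knockdown"),
                   cell_line = paste0("line", seq_len(n_lines)),
                   stringsAsFactors = FALSE)
  s$sample <- with(s, paste(cell_line, condition, replicate, sep = "_"))
  s
}

test_that("CPM filtering follows its definition and thresholds", {
  counts <- rbind(
    kept   = c(2, 2, 2, 0, 0, 0),   # CPM 2 in three samples
    zero   = c(0, 0, 0, 0, 0, 0),
    border = c(1, 1, 1, 1, 1, 1)    # CPM exactly 1: strict > fails
  )
  # filler row pins every library size at exactly 1e6
  counts <- rbind(counts, filler = 1e6 - colSums(counts))
  colnames(counts) <- paste0("s", 1:6)
  ft <- filter_and_transform(counts, min_cpm = 1, min_samples = 3)
  expect_true("kept" %in% rownames(ft$logcpm))
  expect_false("zero" %in% rownames(ft$logcpm))
  expect_false("border" %in% rownames(ft$logcpm))
  # CPM of count 10 in a 1e6 library is 10
  m <- matrix(10, 1, 6, dimnames = list("g", paste0("s", 1:6)))
  m2 <- rbind(m, filler = 1e6 - 10)
  ft2 <- filter_and_transform(m2, min_cpm = 1, min_samples = 3)
  expect_equal(unname(ft2$logcpm["g", 1]), log2(10 + 0.5))
  bad <- cbind(m[, 1:5, drop = FALSE], s6 = 0)
  expect_error(filter_and_transform(bad), "all-zero library: s6")
})

test_that("with the prior turned off the moderated t equals the OLS t", {
  set.seed(31)
  s <- make_samples()
  E <- matrix(rnorm(200 * 12, mean = 5), 200, 12,
              dimnames = list(sprintf("g%03d", 1:200), s$sample))
  fit <- moderated_t_test(E, s, prior_df = 0)
  ref <- oracle_ols_t(E, s)
  expect_equal(fit$table$logFC, unname(ref[, "logFC"]), tolerance = 1e-8)
  expect_equal(fit$table$t, unname(ref[, "t"]), tolerance = 1e-8)
  expect_equal(fit$table$p, unname(ref[, "p"]), tolerance = 1e-8)
})

test_that("an infinite prior pools all posterior variances", {
  set.seed(32)
  s <- make_samples()
  E <- matrix(rnorm(100 * 12), 100, 12,
              dimnames = list(sprintf("g%03d", 1:100), s$sample))
  fit <- moderated_t_test(E, s, prior_df = Inf)
  expect_equal(length(unique(fit$params$s2_post)), 1L)
  # a gene with identical values everywhere is a clean null under moderation
  E2 <- E
  E2[1, ] <- 3
  fit2 <- moderated_t_test(E2, s)
  expect_equal(fit2$table$logFC[1], 0)
  expect_equal(fit2$table$p[1], 1)
})

test_that("the eBayes fit agrees with an independent implementation", {
  skip_if_not_installed("limma")
  set.seed(33)
  s <- make_samples()
  # heterogeneous gene variances so shrinkage is non-trivial
  sd_g <- sqrt(1 / rgamma(300, shape = 4, rate = 2))
  E <- matrix(rnorm(300 * 12, mean = 6, sd = rep(sd_g, 12)), 300, 12,
              dimnames = list(sprintf("g%03d", 1:300), s$sample))
  fit <- moderated_t_test(E, s)
  design <- model.matrix(~ factor(s$condition, c("control", "knockdown")) +
                           factor(s$cell_line))
  lfit <- limma::eBayes(limma::lmFit(E, design))
  expect_equal(fit$params$d0, lfit$df.prior, tolerance = 1e-4)
  expect_equal(fit$params$s0_sq, lfit$s2.prior, tolerance = 1e-4)
  expect_equal(fit$table$t, unname(lfit$t[, 2]), tolerance = 1e-6)
  expect_equal(fit$table$p, unname(lfit$p.value[, 2]), tolerance = 1e-6)
})

test_that("degenerate designs are rejected", {
  s <- make_samples()
  E <- matrix(rnorm(10 * 12), 10, 12,
              dimnames = list(paste0("g", 1:10), s$sample))
  s_one <- s; s_one$condition <- "control"
  expect_error(moderated_t_test(E, s_one), "knockdown and control")
  s2 <- make_samples(n_lines = 1, reps = 1)
  E2 <- matrix(rnorm(10 * 2), 10, 2,
               dimnames = list(paste0("g", 1:10), s2$sample))
  expect_error(moderated_t_test(E2, s2), "degrees of freedom")
})

test_that("regulation calls use BH adjustment and strict thresholds", {
  tab <- data.frame(gene_id = paste0("g", 1:4),
                    logFC = c(2, -2, 0.05, 0.1),
                    p = c(0.01, 0.02, 0.03, 0.04))
  out <- call_de(tab, lfc_threshold = 0.1, alpha = 0.05)
  # hand BH step-up: p * 4 / rank, cumulative minimum from the largest
  expect_equal(out$adj_p, rep(0.04, 4))
  expect_equal(out$call, c("up", "down", "ns", "ns"))
  # logFC 0.05 stays ns even at adj_p 1e-4; threshold itself is exclusive
  tab2 <- data.frame(gene_id = c("a", "b"), logFC = c(0.05, 0.1),
                     p = c(1e-6, 1e-6))
  expect_equal(call_de(tab2)$call, c("ns", "ns"))
  # BH is monotone and bounded by 1
  set.seed(34)
  p <- runif(500)
  adj <- call_de(data.frame(gene_id = paste0("g", 1:500),
                            logFC = 1, p = p))$adj_p
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("planted knockdown effects are recovered on synthetic counts", {
  cfg <- sim_config(seed = 35, n_genes = 800, n_direct_pos = 40,
                    n_direct_neg = 40, n_distal_pos = 0, n_distal_neg = 0,
                    n_indirect = 0, background_peak_count = 0)
  set.seed(35)
  truth <- simulate_truth(cfg)
  cm <- simulate_counts(truth, cfg)
  ft <- filter_and_transform(cm$counts)
  de <- call_de(moderated_t_test(ft$logcpm, cm$samples)$table)
  merged <- merge(de, truth[, c("gene_id", "planted_lfc")], by = "gene_id")
  planted <- merged[merged$planted_lfc != 0, ]
  expect_lt(median(abs(planted$logFC - planted$planted_lfc)), 0.3)
  expect_gte(mean(planted$call != "ns"), 0.9)
})
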