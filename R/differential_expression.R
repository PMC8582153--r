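#' Read a count matrix and sample sheet
#'
#' @param counts_path TSV of gene-level counts, first column `gene_id`, one
#'   column per sample.
#' @param samples_path TSV sample sheet with columns `sample`, `cell_line`,
#'   `condition` (`knockdown`/`control`) and `replicate`.
#' @return list with `counts` (integer matrix, genes x samples) and
#'   `samples` (data.frame, rows aligned with matrix columns).
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  tab <- read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tab)) stop("counts file lacks a gene_id column")
  counts <- as.matrix(tab[, setdiff(names(tab), "gene_id"), drop = FALSE])
  rownames(counts) <- tab$gene_id
  storage.mode(counts) <- "integer"
  samples <- read.delim(samples_path, stringsAsFactors = FALSE)
  need <- c("sample", "cell_line", "condition")
  if (!all(need %in% names(samples)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (!setequal(samples$sample, colnames(counts)))
    stop("sample sheet and count-matrix columns disagree")
  samples <- samples[match(colnames(counts), samples$sample), ]
  if (!all(samples$condition %in% c("knockdown", "control")))
    stop("condition must be 'knockdown' or 'control'")
  if (any(counts < 0, na.rm = TRUE)) stop("negative counts")
  list(counts = counts, samples = samples)
}

#' Expression filtering and log2-CPM transformation
#'
#' Keeps a gene iff its counts-per-million exceed `min_cpm` in at least
#' `min_samples` samples (CPM of count c in a library of size L is
#' `c * 1e6 / L`), then returns `log2(CPM + 0.5)` for the retained genes.
#'
#' @param counts Integer matrix, genes x samples (or the list returned by
#'   [read_count_matrix()]).
#' @param min_cpm CPM threshold (default 1; strict inequality).
#' @param min_samples Minimum number of samples above threshold (default 3).
#' @return list with `logcpm` (matrix of retained genes), `lib_sizes`,
#'   `kept` (logical over input genes).
#' @export
filter_and_transform <- function(counts, min_cpm = 1, min_samples = 3) {
  if (is.list(counts) && !is.matrix(counts)) counts <- counts$counts
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("all-zero library: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  kept <- rowSums(cpm > min_cpm) >= min_samples
  logcpm <- log2(cpm[kept, , drop = FALSE] + 0.5)
  list(logcpm = logcpm, lib_sizes = lib, kept = kept)
}

# Inverse of the trigamma function by Newton iteration on 1/x scale
# (monotone, globally convergent for y > 0).
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

# Empirical-Bayes prior (d0, s0_sq) for gene-wise residual variances s2 with
# d residual df, by matching the first two moments of log(s2) to a
# scaled-inverse-chi-square model.  e_g = log(s2_g) - digamma(d/2) + log(d/2)
# has mean log(s0_sq) + digamma(d0/2) - log(d0/2) and excess variance
# trigamma(d0/2) beyond trigamma(d/2).
.estimate_prior <- function(s2, d) {
  ok <- s2 > 0 & is.finite(s2)
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ev <- var(e) - trigamma(d / 2)
  if (!is.finite(ev) || ev <= 0) {
    # no excess variability: variances fully pooled
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    d0 <- 2 * .trigamma_inverse(ev)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-test for knockdown differential expression
#'
#' Fits, per gene, an ordinary least-squares model of log2-CPM on condition
#' plus a cell-line blocking factor, shrinks the gene-wise residual
#' variances toward an empirically estimated prior, and tests the knockdown
#' coefficient with a moderated t statistic.
#'
#' The posterior variance is `(d0 * s0_sq + d * s2_g) / (d0 + d)` where `d`
#' is the residual df and `(d0, s0_sq)` the prior estimated by closed-form
#' moment matching on `log(s2_g)` (digamma/trigamma inversion). The
#' moderated t is `logFC / (u * s_post)` with `u` the unscaled coefficient
#' standard error, referred to a t distribution on `d0 + d` df. With
#' `prior_df = 0` this reduces exactly to the ordinary OLS t on `d` df; with
#' `prior_df = Inf` all genes share the pooled prior variance.
#'
#' Sign convention: `logFC` is knockdown minus control, so `logFC < 0` after
#' TF knockdown means the gene is positively regulated by the TF.
#'
#' @param logexpr Matrix of log2 expression, genes x samples.
#' @param samples data.frame with `condition` (`knockdown`/`control`) and
#'   `cell_line` per column of `logexpr`.
#' @param prior_df Optional override of the prior df `d0`: `NULL` (default)
#'   estimates it; `0` gives the ordinary t; `Inf` fully pools variances.
#' @param block_cell_line Include the cell-line blocking factor (default
#'   TRUE; ignored when only one cell line is present).
#' @return list with `table` (data.frame: `gene_id`, `logFC`, `t`, `p`) and
#'   `params` (list `d0`, `s0_sq`, `df_residual`, `df_total`).
#' @export
moderated_t_test <- function(logexpr, samples, prior_df = NULL,
                             block_cell_line = TRUE) {
  stopifnot(ncol(logexpr) == nrow(samples))
  cond <- factor(samples$condition, levels = c("control", "knockdown"))
  if (nlevels(droplevels(cond)) < 2)
    stop("both knockdown and control samples are required")
  if (block_cell_line && length(unique(samples$cell_line)) > 1)
    X <- model.matrix(~ cond + factor(samples$cell_line))
  else
    X <- model.matrix(~ cond)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular design matrix")
  n <- nrow(X); p <- ncol(X)
  d <- n - p
  if (d < 2) stop("fewer than 2 residual degrees of freedom")
  beta <- t(qr.coef(qrX, t(logexpr)))
  res <- t(qr.resid(qrX, t(logexpr)))
  s2 <- rowSums(res^2) / d
  XtX_inv <- chol2inv(qr.R(qrX))
  u <- sqrt(XtX_inv[2, 2])  # unscaled SE of the knockdown coefficient
  logFC <- beta[, 2]

  if (is.null(prior_df)) {
    pr <- tryCatch(.estimate_prior(s2, d), error = function(e) NULL)
    if (is.null(pr)) {
      warning("prior estimation failed; falling back to ordinary t (d0 = 0)")
      pr <- list(d0 = 0, s0_sq = NA_real_)
    }
  } else {
    d0 <- prior_df
    s0_sq <- if (is.finite(d0) && d0 == 0) NA_real_ else
      .estimate_prior(s2, d)$s0_sq
    pr <- list(d0 = d0, s0_sq = s0_sq)
  }
  d0 <- pr$d0; s0_sq <- pr$s0_sq
  if (!is.finite(d0)) {
    s2_post <- rep(s0_sq, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- d
  } else {
    s2_post <- (d0 * s0_sq + d * s2) / (d0 + d)
    df_total <- d0 + d
  }
  tstat <- logFC / (u * sqrt(s2_post))
  pval <- 2 * pt(abs(tstat), df = df_total, lower.tail = FALSE)
  list(
    table = data.frame(gene_id = rownames(logexpr), logFC = logFC,
                       t = tstat, p = pval, stringsAsFactors = FALSE,
                       row.names = NULL),
    params = list(d0 = d0, s0_sq = s0_sq, df_residual = d,
                  df_total = df_total, s2 = s2, s2_post = s2_post)
  )
}

#' Regulation calls from differential-expression results
#'
#' Benjamini-Hochberg adjusts the p-values over all tested genes, then
#' calls a gene `up` if `logFC > lfc_threshold` and `adj_p < alpha`, `down`
#' if `logFC < -lfc_threshold` and `adj_p < alpha`, else `ns`. All
#' inequalities are strict (a gene at exactly the fold-change threshold is
#' `ns`).
#'
#' @param de_table data.frame with `gene_id`, `logFC`, `p` (output of
#'   [moderated_t_test()]).
#' @param lfc_threshold Absolute log2-fold-change threshold (default 0.1).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return The table with added `adj_p` and `call` columns.
#' @export
call_de <- function(de_table, lfc_threshold = 0.1, alpha = 0.05) {
  if (is.list(de_table) && !is.data.frame(de_table)) de_table <- de_table$table
  stopifnot(all(de_table$p >= 0 & de_table$p <= 1, na.rm = TRUE))
  de_table$adj_p <- p.adjust(de_table$p, method = "BH")
  de_table$call <- with(de_table, ifelse(
    adj_p < alpha & logFC > lfc_threshold, "up",
    ifelse(adj_p < alpha & logFC < -lfc_threshold, "down", "ns")))
  de_table$call[is.na(de_table$call)] <- "ns"
  de_table
}
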