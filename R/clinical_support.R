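#' Read a clinical expression matrix and subtype annotation
#'
#' @param expr_path TSV of log-scale expression, first column `gene_id`,
#'   one column per specimen. Rows containing missing values are dropped
#'   with a warning.
#' @param samples_path TSV with columns `sample` and `subtype`
#'   (`GCB`/`ABC`/`other`).
#' @return list with `expr` (numeric matrix) and `samples` (data.frame
#'   aligned with the matrix columns).
#' @export
read_expression_matrix <- function(expr_path, samples_path) {
  tab <- read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tab)) stop("expression file lacks a gene_id column")
  expr <- as.matrix(tab[, setdiff(names(tab), "gene_id"), drop = FALSE])
  rownames(expr) <- tab$gene_id
  ok <- complete.cases(expr)
  if (!all(ok)) {
    warning(sum(!ok), " gene row(s) with missing values dropped")
    expr <- expr[ok, , drop = FALSE]
  }
  samples <- read.delim(samples_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "subtype") %in% names(samples)))
    stop("sample sheet must have columns sample, subtype")
  if (!setequal(samples$sample, colnames(expr)))
    stop("sample sheet and expression columns disagree")
  samples <- samples[match(colnames(expr), samples$sample), ]
  list(expr = expr, samples = samples)
}

#' Correlation screen against the transcription factor
#'
#' Pearson correlation of every gene's expression with the TF's expression
#' across specimens; two-sided p from `t = r * sqrt((n-2)/(1-r^2))` on
#' `n - 2` df. The TF row itself is excluded, zero-variance genes are
#' skipped with a warning, and only genes with `p < alpha` are returned.
#'
#' @param expr Numeric matrix, genes x samples (or the list from
#'   [read_expression_matrix()]).
#' @param tf_gene Row name of the transcription factor.
#' @param alpha Significance threshold (default 0.01, strict).
#' @param subtype_filter Optional: restrict the screen to specimens of this
#'   subtype (requires `expr` to be the list form with a sample sheet).
#' @return data.frame with `gene_id`, `r`, `p`, `sign` for significant
#'   genes only, ordered by p.
#' @export
correlation_screen <- function(expr, tf_gene, alpha = 0.01,
                               subtype_filter = NULL) {
  samples <- NULL
  if (is.list(expr) && !is.matrix(expr)) {
    samples <- expr$samples
    expr <- expr$expr
  }
  if (!is.null(subtype_filter)) {
    if (is.null(samples))
      stop("subtype_filter requires an expression list with a sample sheet")
    expr <- expr[, samples$subtype %in% subtype_filter, drop = FALSE]
  }
  if (!tf_gene %in% rownames(expr)) stop("TF gene not in matrix: ", tf_gene)
  n <- ncol(expr)
  if (n < 4) stop("at least 4 specimens required")
  tf <- expr[tf_gene, ]
  others <- expr[setdiff(rownames(expr), tf_gene), , drop = FALSE]
  v <- apply(others, 1, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) skipped")
    others <- others[v > 0, , drop = FALSE]
  }
  if (var(tf) == 0) stop("TF expression has zero variance")
  r <- as.numeric(cor(t(others), tf))
  r_c <- pmin(pmax(r, -1), 1)
  tstat <- r_c * sqrt((n - 2) / pmax(1 - r_c^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  out <- data.frame(gene_id = rownames(others), r = r, p = p,
                    sign = ifelse(r >= 0, "+", "-"),
                    stringsAsFactors = FALSE)
  out <- out[out$p < alpha, , drop = FALSE]
  out[order(out$p), , drop = FALSE]
}

#' Median dichotomization and subtype contingency test
#'
#' Splits specimens into high (`> median`) and low (`<= median`; ties go to
#' low) TF expressors using the median over all included specimens, builds
#' the 2x2 table of high/low against GCB/ABC subtype, and tests association
#' with a two-sided Fisher exact test. The odds ratio is the sample
#' cross-product ratio with the Haldane 0.5 correction when a cell is zero.
#'
#' @param expr Expression matrix (or the list from
#'   [read_expression_matrix()], whose sample sheet supplies the subtypes).
#' @param tf_gene Row name of the transcription factor.
#' @param subtypes Character vector of per-specimen subtypes (not needed in
#'   the list form). Specimens outside `GCB`/`ABC` are excluded.
#' @return list with `table` (2x2: high/low x GCB/ABC), `odds_ratio`, `p`.
#' @export
dichotomize_and_test <- function(expr, tf_gene, subtypes = NULL) {
  if (is.list(expr) && !is.matrix(expr)) {
    if (is.null(subtypes)) subtypes <- expr$samples$subtype
    expr <- expr$expr
  }
  if (!tf_gene %in% rownames(expr)) stop("TF gene not in matrix: ", tf_gene)
  stopifnot(length(subtypes) == ncol(expr))
  keep <- subtypes %in% c("GCB", "ABC")
  x <- expr[tf_gene, keep]
  st <- factor(subtypes[keep], levels = c("GCB", "ABC"))
  if (any(table(st) == 0)) stop("both GCB and ABC groups must be nonempty")
  if (length(unique(x)) == 1)
    stop("all specimens have identical TF expression; dichotomization undefined")
  med <- median(x)
  grp <- factor(ifelse(x > med, "high", "low"), levels = c("high", "low"))
  tab <- table(grp, st)
  ft <- fisher.test(tab, alternative = "two.sided")
  t2 <- tab + if (any(tab == 0)) 0.5 else 0
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(table = tab, odds_ratio = unname(or), p = ft$p.value)
}
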