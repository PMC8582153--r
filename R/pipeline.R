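#' Run the full direct-target pipeline from a configuration
#'
#' Executes every stage in dependency order: annotation and promoter
#' windows, peak loading and context annotation, promoter gene sets, CPM
#' filtering and the moderated t-test with BH calls, enhancer linkage of
#' distal peaks, clinical correlation screen and median-dichotomization
#' contingency test, direct-target calling and evidence tiering, optional
#' motif enrichment and over-representation analysis. Writes intermediate
#' TSVs, a `summary.json` with the integration counts, and a run log.
#'
#' @param config Path to a YAML file, or an equivalent named list, with
#'   entries: `annotation` (+ optional `annotation_format`), `peaks` (named
#'   map cell line -> BED path), `counts`, `samples`, `interactions`,
#'   `clinical`, `clinical_samples`, `essential`, `tf_gene`, optional
#'   `peak_fasta`, `pwm`, `gmt`, and a `thresholds` block (`flank`,
#'   `min_cpm`, `min_samples`, `lfc`, `alpha_de`, `alpha_corr`), plus
#'   `seed`. Stages whose inputs are absent are skipped, except that
#'   `interactions` is required when `distal: true` is set.
#' @param outdir Output directory.
#' @return Invisibly, a list with all stage results and the summary.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  th <- config$thresholds
  flank <- th$flank %||% 3000
  min_cpm <- th$min_cpm %||% 1
  min_samples <- th$min_samples %||% 3
  lfc <- th$lfc %||% 0.1
  alpha_de <- th$alpha_de %||% 0.05
  alpha_corr <- th$alpha_corr %||% 0.01
  seed <- config$seed %||% 1L

  required <- c("annotation", "peaks", "counts", "samples")
  missing <- required[!required %in% names(config)]
  if (length(missing) > 0)
    stop("configuration error: missing entries ",
         paste(missing, collapse = ", "))
  if (isTRUE(config$distal) && is.null(config$interactions))
    stop("configuration error: distal stage enabled but no interaction map")
  paths <- unlist(config[intersect(names(config),
                                   c("annotation", "counts", "samples",
                                     "interactions", "clinical",
                                     "clinical_samples", "essential",
                                     "peak_fasta", "pwm", "gmt"))])
  paths <- c(paths, unlist(config$peaks))
  absent <- paths[!file.exists(paths)]
  if (length(absent) > 0)
    stop("configuration error: input file(s) not found: ",
         paste(absent, collapse = ", "))

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  log_lines <- c(
    paste0("tfdirect ", as.character(utils::packageVersion("tfdirect"))),
    paste0("R ", R.version.string),
    paste0("seed ", seed),
    paste0("thresholds flank=", flank, " min_cpm=", min_cpm,
           " min_samples=", min_samples, " lfc=", lfc,
           " alpha_de=", alpha_de, " alpha_corr=", alpha_corr))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ann <- stage("annotation", read_gene_annotation(
    config$annotation, config$annotation_format %||% "gtf"))
  win <- stage("promoter_windows", promoter_windows(ann, flank))
  annotated <- stage("peak_annotation", {
    lapply(setNames(nm = names(config$peaks)), function(ln)
      annotate_peaks(read_peaks(config$peaks[[ln]], ln), ann, win))
  })
  pooled_peaks <- do.call(c, unname(annotated))
  sets <- stage("promoter_gene_sets", promoter_gene_sets(annotated))
  ctx <- stage("context_distribution", context_distribution(annotated))

  de <- stage("differential_expression", {
    cm <- read_count_matrix(config$counts, config$samples)
    ft <- filter_and_transform(cm$counts, min_cpm, min_samples)
    fit <- moderated_t_test(ft$logcpm, cm$samples)
    list(table = call_de(fit$table, lfc, alpha_de), params = fit$params,
         universe = rownames(ft$logcpm))
  })

  linked <- list(); distal_only <- character(0)
  if (!is.null(config$interactions)) {
    linked <- stage("chic_linkage", {
      imap <- read_interaction_map(config$interactions)
      link_distal_peaks(pooled_peaks, imap, flank)
    })
    distal_only <- distal_only_genes(linked, sets$union)
  }

  correlations <- data.frame(gene_id = character(0), r = numeric(0),
                             p = numeric(0), sign = character(0))
  contingency <- NULL
  if (!is.null(config$clinical)) {
    clin <- stage("clinical_support", read_expression_matrix(
      config$clinical, config$clinical_samples))
    correlations <- stage("correlation_screen", correlation_screen(
      clin, config$tf_gene %||% "TF1", alpha_corr,
      subtype_filter = config$subtype_filter))
    contingency <- stage("dichotomize_and_test",
                         dichotomize_and_test(clin,
                                              config$tf_gene %||% "TF1"))
  }
  essentials <- if (!is.null(config$essential))
    stage("essential_genes", read_essential_genes(config$essential))
  else character(0)

  targets <- stage("target_integration", {
    tier_targets(call_direct_targets(de$table, sets$union, distal_only),
                 correlations, essentials)
  })
  summary <- summarize_targets(targets)
  summary$context_fractions <- as.list(ctx)
  summary$promoter_gene_sets <- list(
    per_line = lapply(sets$per_line, length),
    union = length(sets$union), common = length(sets$common))
  summary$n_distal_linked <- length(linked)
  summary$n_distal_only <- length(distal_only)
  if (!is.null(contingency))
    summary$dichotomization <- list(odds_ratio = contingency$odds_ratio,
                                    p = contingency$p)

  motif <- NULL
  if (!is.null(config$peak_fasta) && !is.null(config$pwm)) {
    motif <- stage("motif_enrichment", {
      seqs <- read_fasta_sequences(config$peak_fasta)
      pwms <- read_jaspar(config$pwm)
      enrichment_test(seqs, pwms[[1]], seed = as.integer(seed))
    })
    summary$motif <- list(fold = motif$fold, p = motif$p)
  }
  ora <- NULL
  if (!is.null(config$gmt)) {
    ora <- stage("ora", {
      coll <- gene_set_collection(read_gmt(config$gmt), de$universe)
      q <- targets$gene_id[targets$direct]
      if (length(q) > 0) hypergeometric_ora(q, coll) else NULL
    })
  }

  fp <- function(x) file.path(outdir, x)
  for (ln in names(annotated))
    write_annotated_peaks(annotated[[ln]],
                          fp(paste0("annotated_peaks_", ln, ".tsv")))
  write.table(de$table, fp("de_results.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(targets, fp("targets.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (nrow(correlations) > 0)
    write.table(correlations, fp("correlations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (length(distal_only) > 0)
    write.table(data.frame(gene_id = distal_only), fp("distal_only.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ora))
    write.table(ora, fp("ora_results.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(log_lines, fp("run_log.txt"))

  invisible(list(annotation = ann, annotated_peaks = annotated,
                 promoter_sets = sets, context = ctx, de = de,
                 linked = linked, distal_only = distal_only,
                 correlations = correlations, contingency = contingency,
                 targets = targets, summary = summary, motif = motif,
                 ora = ora, outdir = outdir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
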