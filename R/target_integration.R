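#' Call direct transcription-factor targets
#'
#' Intersects binding evidence with the knockdown differential-expression
#' calls. A gene is a direct promoter target iff it is in the
#' promoter-bound union and its DE call is not `ns`; a distal direct target
#' iff it is in the distal-only set and its DE call is not `ns`. Regulation
#' follows the knockdown sign convention: a gene that goes down after TF
#' knockdown (`call == "down"`) is positively regulated by the TF, a gene
#' that goes up is negatively regulated.
#'
#' @param de_results data.frame from [call_de()] (`gene_id`, `logFC`,
#'   `adj_p`, `call`).
#' @param promoter_gene_union Character vector: promoter-bound genes.
#' @param distal_only_genes Character vector: distal-only linked genes
#'   (default empty).
#' @return data.frame of `TargetCall`s over all DE-tested genes: `gene_id`,
#'   `binding` (`promoter`/`distal_only`/`none`), `de_call`, `regulation`
#'   (`positive`/`negative`/`none`), `direct` (logical), `logFC`, `adj_p`.
#' @export
call_direct_targets <- function(de_results, promoter_gene_union,
                                distal_only_genes = character(0)) {
  both <- intersect(promoter_gene_union, distal_only_genes)
  if (length(both) > 0)
    stop("promoter and distal-only sets must be disjoint; offending genes: ",
         paste(head(both, 5), collapse = ", "))
  binding <- ifelse(de_results$gene_id %in% promoter_gene_union, "promoter",
                    ifelse(de_results$gene_id %in% distal_only_genes,
                           "distal_only", "none"))
  regulation <- ifelse(de_results$call == "down", "positive",
                       ifelse(de_results$call == "up", "negative", "none"))
  data.frame(
    gene_id = de_results$gene_id,
    binding = binding,
    de_call = de_results$call,
    regulation = regulation,
    direct = binding != "none" & de_results$call != "ns",
    logFC = de_results$logFC,
    adj_p = de_results$adj_p,
    stringsAsFactors = FALSE
  )
}

#' Add clinical-correlation and essentiality evidence tiers
#'
#' A target has clinical support when it is significant in the correlation
#' screen *and* the correlation sign is concordant with its regulation
#' (positive regulation by the TF pairs with r > 0, negative with r < 0);
#' concordance can be disabled. Essentiality is membership in the
#' essential-gene list. The evidence tier counts accumulated evidence:
#' tier 1 = binding + DE (a direct target), tier 2 adds clinical support,
#' tier 3 adds essentiality on top of clinical support; clinical support
#' and essentiality are also reported as independent flags because
#' essentiality does not require clinical support.
#'
#' @param targets data.frame from [call_direct_targets()].
#' @param correlations data.frame from [correlation_screen()].
#' @param essentials Character vector of essential gene ids (may be empty).
#' @param require_concordance Require sign concordance for clinical support
#'   (default TRUE).
#' @return The targets data.frame with added `clinical_support`,
#'   `essential`, `tier` (0 for non-targets; 1 + number of extra evidence
#'   layers for direct targets).
#' @export
tier_targets <- function(targets, correlations, essentials = character(0),
                         require_concordance = TRUE) {
  idx <- match(targets$gene_id, correlations$gene_id)
  r <- correlations$r[idx]
  significant <- !is.na(idx)
  concordant <- (targets$regulation == "positive" & r > 0) |
    (targets$regulation == "negative" & r < 0)
  concordant[is.na(concordant)] <- FALSE
  targets$clinical_support <- significant &
    (if (require_concordance) concordant else TRUE) &
    targets$regulation != "none"
  targets$essential <- targets$gene_id %in% essentials
  targets$tier <- ifelse(!targets$direct, 0L,
                         1L + as.integer(targets$clinical_support) +
                           as.integer(targets$essential))
  targets
}

#' Summary counts of the target-calling run
#'
#' Mirrors the integration table: per-regulation counts of direct promoter
#' and distal-only targets, of clinically supported targets and of
#' essential-gene overlaps, all recomputed from the target table itself.
#'
#' @param targets Tiered targets data.frame from [tier_targets()].
#' @return Nested list of counts (suitable for JSON serialization).
#' @export
summarize_targets <- function(targets) {
  d <- targets[targets$direct, , drop = FALSE]
  cnt <- function(x) as.integer(sum(x))
  by_reg <- function(df) list(
    positive = cnt(df$regulation == "positive"),
    negative = cnt(df$regulation == "negative"))
  list(
    n_genes_tested = nrow(targets),
    promoter_bound = cnt(targets$binding == "promoter"),
    distal_only_bound = cnt(targets$binding == "distal_only"),
    de = list(up = cnt(targets$de_call == "up"),
              down = cnt(targets$de_call == "down"),
              ns = cnt(targets$de_call == "ns")),
    direct = by_reg(d),
    direct_promoter = by_reg(d[d$binding == "promoter", , drop = FALSE]),
    direct_distal = by_reg(d[d$binding == "distal_only", , drop = FALSE]),
    clinical_confirmed = by_reg(d[d$clinical_support, , drop = FALSE]),
    essential_overlap = by_reg(d[d$essential, , drop = FALSE])
  )
}

#' Read an essential-gene list
#'
#' @param path TSV with a `gene_id` column (or a single unnamed column).
#' @return Character vector of gene ids.
#' @export
read_essential_genes <- function(path) {
  if (!file.exists(path)) stop("essential-gene file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  ids <- if ("gene_id" %in% names(tab)) tab$gene_id else tab[[1]]
  ids <- unique(as.character(ids))
  if (length(ids) == 0) stop("essential-gene list is empty")
  ids
}
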