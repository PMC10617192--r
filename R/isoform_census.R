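#' Apply the expression floor at gene level
#'
#' A gene is retained iff the mean over all samples of its summed
#' per-transcript FPKM is strictly greater than `min_mean_fpkm`
#' (default 1 FPKM). With `transcript_floor = TRUE`, transcripts whose own
#' mean FPKM across all samples is at or below the floor are dropped
#' before genes are summed — an alternative, stricter reading of the
#' expression filter applied per transcript.
#'
#' @param table An [expression_table()].
#' @param min_mean_fpkm Expression floor (strict `>`).
#' @param transcript_floor Apply the floor per transcript first.
#' @return Character vector of retained gene ids.
#' @export
filter_expressed_genes <- function(table, min_mean_fpkm = 1,
                                   transcript_floor = FALSE) {
  stopifnot(inherits(table, "ExpressionTable"))
  if (transcript_floor) {
    keep <- rowMeans(table$fpkm) > min_mean_fpkm
    if (!any(keep)) return(character())
    table <- expression_table(table$fpkm[keep, , drop = FALSE],
                              table$tx2gene[keep], table$design)
  }
  g <- gene_fpkm(table)
  rownames(g)[rowMeans(g) > min_mean_fpkm]
}

#' Count isoforms per expressed gene and select the two-isoform set
#'
#' Builds the isoform-count histogram over the expressed genes and
#' partitions them into single-isoform genes (not analyzable for isoform
#' switching), two-isoform genes (the analysis set) and genes with three
#' or more isoforms (counted but excluded from downstream analysis).
#'
#' @param models Named list of [gene_model()] objects.
#' @param expressed Character vector of expressed gene ids; every id must
#'   have a model.
#' @return An object of class `CensusResult`: `expressed_genes`,
#'   `histogram` (named integer vector isoform count -> gene count),
#'   `two_isoform_genes`, `excluded_single`, `excluded_many`.
#' @export
census <- function(models, expressed) {
  missing_m <- setdiff(expressed, names(models))
  if (length(missing_m))
    stop("expressed genes without a model: ",
         paste(utils::head(missing_m, 5), collapse = ", "))
  counts <- vapply(models[expressed], function(gm) length(gm$transcripts),
                   integer(1))
  histogram <- table(factor(counts))
  histogram <- stats::setNames(as.integer(histogram), names(histogram))
  two <- names(counts)[counts == 2L]
  structure(list(expressed_genes = expressed,
                 histogram = histogram,
                 two_isoform_genes = sort(two),
                 excluded_single = sum(counts == 1L),
                 excluded_many = sum(counts >= 3L)),
            class = "CensusResult")
}

# integer percentage truncated toward zero; 974/1235 multi-isoform genes
# with two isoforms prints as 78
truncated_percent <- function(numerator, denominator) {
  if (denominator == 0) return(NA_integer_)
  as.integer(trunc(100 * numerator / denominator))
}

#' Summarize the census funnel
#'
#' @param result A [census()] result.
#' @return Data frame with one row: expressed, single-, two- and
#'   many-isoform gene counts, the multi-isoform count, and the
#'   percentage (integer, truncated) of multi-isoform genes with exactly
#'   two isoforms (`NA` when there are no multi-isoform genes).
#' @export
report_funnel <- function(result) {
  stopifnot(inherits(result, "CensusResult"))
  h <- result$histogram
  n_two <- if ("2" %in% names(h)) h[["2"]] else 0L
  n_multi <- sum(h[as.integer(names(h)) >= 2L])
  data.frame(
    expressed = length(result$expressed_genes),
    single_isoform = result$excluded_single,
    two_isoform = n_two,
    three_or_more = result$excluded_many,
    multi_isoform = n_multi,
    two_isoform_percent = truncated_percent(n_two, n_multi))
}
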