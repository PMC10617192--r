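#' Threshold set for the CTSAI filter cascade
#'
#' Defaults follow the published cutoffs: per-isoform soma/gonidia
#' expression ratio above 2 (or below 1/2), combined between-isoform bias
#' above 8, per-isoform differential-expression p-value below 0.1, hence
#' an aggregate (product) p-value below 0.01. All inequalities are
#' strict; ties fail.
#'
#' @param tau_bias Per-isoform expression-ratio cutoff.
#' @param tau_B Combined-bias cutoff (ratio of the two isoforms' ERs).
#' @param tau_p Per-isoform p-value cutoff.
#' @param tau_aggregate Aggregate p-value cutoff; defaults to `tau_p^2`.
#' @param pseudocount FPKM pseudocount added to both cell-type means when
#'   forming ratios, guarding against zero denominators. Much smaller
#'   than the 1-FPKM expression floor so ratios of expressed transcripts
#'   are barely perturbed.
#' @return An object of class `Thresholds`.
#' @export
ctsai_thresholds <- function(tau_bias = 2, tau_B = 8, tau_p = 0.1,
                             tau_aggregate = tau_p^2, pseudocount = 0.01) {
  vals <- c(tau_bias, tau_B, tau_p, tau_aggregate)
  if (any(vals <= 0) || pseudocount < 0)
    stop("thresholds must be strictly positive")
  structure(list(tau_bias = tau_bias, tau_B = tau_B, tau_p = tau_p,
                 tau_aggregate = tau_aggregate, pseudocount = pseudocount),
            class = "Thresholds")
}

#' Two-group differential test on log2(FPKM + 1)
#'
#' F-test of the cell-type term in a linear model on log2(FPKM + 1),
#' which for two groups equals a two-sided pooled-variance t-test.
#' Degenerate contract for noise-free data: when the within-group
#' variance is zero in both groups, the p-value is 1 if the group means
#' are equal and 0 otherwise.
#'
#' @param soma_values,gonidia_values Numeric vectors of FPKM (>= 0), at
#'   least 2 values per group.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
two_group_isoform_test <- function(soma_values, gonidia_values) {
  if (length(soma_values) < 2L || length(gonidia_values) < 2L)
    stop("need >= 2 replicates per cell type for the differential test")
  if (any(soma_values < 0) || any(gonidia_values < 0))
    stop("FPKM values must be non-negative")
  ys <- log2(soma_values + 1)
  yg <- log2(gonidia_values + 1)
  if (stats::var(ys) == 0 && stats::var(yg) == 0)
    return(if (mean(ys) == mean(yg)) 1 else 0)
  y <- c(ys, yg)
  g <- factor(rep(c("soma", "gonidia"),
                  c(length(ys), length(yg))))
  stats::anova(stats::lm(y ~ g))[["Pr(>F)"]][1L]
}

#' Per-isoform cell-type expression statistics
#'
#' Computes cell-type mean FPKM, the soma/gonidia expression ratio
#' (with pseudocount in numerator and denominator), its log2, and the
#' two-group differential p-value for one transcript.
#'
#' @param table An [expression_table()] with >= 2 replicates per cell
#'   type.
#' @param transcript_id Transcript to evaluate.
#' @param thresholds A [ctsai_thresholds()] (supplies the pseudocount).
#' @param test Set `FALSE` to skip the differential test (p reported as
#'   `NA`); with `TRUE`, fewer than 2 replicates in either group is an
#'   error.
#' @return An object of class `IsoformStats` with fields
#'   `transcript_id`, `mean_soma`, `mean_gonidia`, `ER`, `log2ER`,
#'   `p_value`.
#' @export
isoform_cell_type_stats <- function(table, transcript_id,
                                    thresholds = ctsai_thresholds(),
                                    test = TRUE) {
  stopifnot(inherits(table, "ExpressionTable"))
  if (!transcript_id %in% rownames(table$fpkm))
    stop("transcript ", transcript_id, " not in expression table")
  soma <- table$fpkm[transcript_id, samples_of(table$design, "soma")]
  gonidia <- table$fpkm[transcript_id, samples_of(table$design, "gonidia")]
  eps <- thresholds$pseudocount
  ms <- mean(soma); mg <- mean(gonidia)
  er <- (ms + eps) / (mg + eps)
  p <- if (test) two_group_isoform_test(soma, gonidia) else NA_real_
  structure(list(transcript_id = transcript_id, mean_soma = ms,
                 mean_gonidia = mg, ER = er, log2ER = log2(er),
                 p_value = p),
            class = "IsoformStats")
}

#' Apply the three-stage filter cascade to one two-isoform gene
#'
#' Isoforms are ordered so iso1 is the higher-ER (more soma-biased)
#' isoform, making the combined bias `B = ER1 / ER2 >= 1` and the
#' cascade orientation-free. Stage 1: opposite biases (`max ER >
#' tau_bias` and `min ER < 1/tau_bias`; equivalently |log2 ER| > 1 on
#' both, with opposite signs, at the default `tau_bias = 2`). Stage 2:
#' stage 1 and `B > tau_B`. Stage 3: stage 2 and both per-isoform
#' p-values `< tau_p` (so the aggregate product is `< tau_p^2`). The
#' verdict is `candidate` iff stage 3 passes.
#'
#' @param gene_id Gene identifier.
#' @param stats_pair List of exactly two [isoform_cell_type_stats()]
#'   results.
#' @param thresholds A [ctsai_thresholds()].
#' @param source Annotation source tag carried into the record.
#' @return An object of class `CandidateRecord`.
#' @export
apply_filter_cascade <- function(gene_id, stats_pair,
                                 thresholds = ctsai_thresholds(),
                                 source = "ballgown") {
  if (length(stats_pair) != 2L)
    stop("gene ", gene_id, ": filter cascade needs exactly two isoforms")
  ers <- vapply(stats_pair, `[[`, numeric(1), "ER")
  ord <- order(ers, decreasing = TRUE)
  iso1 <- stats_pair[[ord[1L]]]
  iso2 <- stats_pair[[ord[2L]]]
  b <- iso1$ER / iso2$ER
  s1 <- iso1$ER > thresholds$tau_bias && iso2$ER < 1 / thresholds$tau_bias
  s2 <- s1 && b > thresholds$tau_B
  p_ok <- !is.na(iso1$p_value) && !is.na(iso2$p_value) &&
    iso1$p_value < thresholds$tau_p && iso2$p_value < thresholds$tau_p
  s3 <- s2 && p_ok
  agg <- iso1$p_value * iso2$p_value
  structure(list(gene_id = gene_id, source = source, iso1 = iso1,
                 iso2 = iso2, B = b, aggregate_p = agg,
                 passed_stage1 = s1, passed_stage2 = s2,
                 passed_stage3 = s3,
                 verdict = if (s3) "candidate" else "rejected"),
            class = "CandidateRecord")
}

#' Run CTSAI detection over the two-isoform analysis set
#'
#' Evaluates the filter cascade for every two-isoform gene of a census,
#' producing one candidate record per gene and the per-stage funnel
#' counts (input genes, then survivors of stages 1-3).
#'
#' @param table An [expression_table()].
#' @param models Named list of [gene_model()] objects.
#' @param census_result A [census()] result.
#' @param thresholds A [ctsai_thresholds()].
#' @param source Annotation source tag.
#' @return List with `records` (candidate records in gene_id order) and
#'   `funnel` (data frame: n_input, stage1, stage2, stage3 counts).
#' @export
run_detection <- function(table, models, census_result,
                          thresholds = ctsai_thresholds(),
                          source = "ballgown") {
  stopifnot(inherits(census_result, "CensusResult"))
  genes <- sort(census_result$two_isoform_genes)
  records <- lapply(genes, function(gid) {
    tids <- vapply(models[[gid]]$transcripts, `[[`, character(1),
                   "transcript_id")
    pair <- lapply(tids, function(tid)
      isoform_cell_type_stats(table, tid, thresholds))
    apply_filter_cascade(gid, pair, thresholds, source)
  })
  funnel <- data.frame(
    n_input = length(records),
    stage1 = sum(vapply(records, `[[`, logical(1), "passed_stage1")),
    stage2 = sum(vapply(records, `[[`, logical(1), "passed_stage2")),
    stage3 = sum(vapply(records, `[[`, logical(1), "passed_stage3")))
  list(records = records, funnel = funnel)
}
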