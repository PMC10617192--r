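#' @keywords internal
"_PACKAGE"

#' End-to-end CTSAI detection pipeline
#'
#' Runs the standard chain on one annotation source: gene-level
#' expression floor, isoform census, and the three-stage filter cascade
#' over the two-isoform analysis set. Curation against coverage tracks
#' is a separate step ([curate()]) because it needs per-base coverage.
#'
#' @param table An [expression_table()].
#' @param models Named list of [gene_model()] objects covering every
#'   expressed gene.
#' @param thresholds A [ctsai_thresholds()].
#' @param min_mean_fpkm Expression floor.
#' @param transcript_floor Apply the floor per transcript first (see
#'   [filter_expressed_genes()]).
#' @param source Annotation source tag.
#' @return List with `expressed` (gene ids), `census` (a `CensusResult`),
#'   `funnel` (census funnel row), `detection` (records + stage funnel
#'   from [run_detection()]) and `candidates` (gene ids with verdict
#'   `candidate`).
#' @export
detect_ctsai <- function(table, models,
                         thresholds = ctsai_thresholds(),
                         min_mean_fpkm = 1, transcript_floor = FALSE,
                         source = "ballgown") {
  expressed <- filter_expressed_genes(table, min_mean_fpkm,
                                      transcript_floor)
  cens <- census(models, expressed)
  det <- run_detection(table, models, cens, thresholds, source)
  verdicts <- vapply(det$records, `[[`, character(1), "verdict")
  list(expressed = expressed, census = cens,
       funnel = report_funnel(cens), detection = det,
       candidates = vapply(det$records, `[[`, character(1),
                           "gene_id")[verdicts == "candidate"])
}
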