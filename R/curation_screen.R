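#' Differential and shared regions of a two-isoform pair
#'
#' Exact interval set differences and intersection of the two isoforms'
#' exonic unions, in 0-based half-open coordinates. The three interval
#' sets are pairwise disjoint and partition the union of both exonic
#' footprints.
#'
#' @param iso1,iso2 [transcript_model()] objects on the same chromosome.
#' @return An object of class `DifferentialRegions`: `gene_id`, `chrom`,
#'   and interval matrices `unique_to_iso1`, `unique_to_iso2`, `shared`.
#' @export
differential_regions <- function(iso1, iso2) {
  if (iso1$chrom != iso2$chrom)
    stop("isoforms on different chromosomes: ", iso1$chrom, " vs ",
         iso2$chrom)
  a <- IRanges::reduce(exons_to_iranges(iso1$exons))
  b <- IRanges::reduce(exons_to_iranges(iso2$exons))
  structure(list(gene_id = iso1$gene_id, chrom = iso1$chrom,
                 unique_to_iso1 = iranges_to_exons(IRanges::setdiff(a, b)),
                 unique_to_iso2 = iranges_to_exons(IRanges::setdiff(b, a)),
                 shared = iranges_to_exons(IRanges::intersect(a, b))),
            class = "DifferentialRegions")
}

#' Read-density curation check (RD)
#'
#' Formalizes the read-density criterion: in the cell type where an
#' isoform is claimed expressed, its unique regions must show mean depth
#' at or above `min_mean_depth` and a fraction of covered (depth > 0)
#' bases at or above `min_covered_fraction`. Both cutoffs are inclusive
#' and artifact-chosen, not taken from any published value. An isoform
#' with no unique region passes vacuously (its structure is the shared
#' structure).
#'
#' @param coverage A [coverage_track()].
#' @param regions A [differential_regions()] result.
#' @param claim_iso1,claim_iso2 Cell type (`"soma"`/`"gonidia"`) in which
#'   each isoform is claimed expressed (from the sign of its ER).
#' @param min_mean_depth Minimum mean depth over unique regions.
#' @param min_covered_fraction Minimum fraction of bases with depth > 0.
#' @return List with per-isoform pass flags (`iso1_pass`, `iso2_pass`),
#'   the combined `rd_pass`, and the per-isoform depth summaries.
#' @export
read_density_check <- function(coverage, regions,
                               claim_iso1 = "soma",
                               claim_iso2 = "gonidia",
                               min_mean_depth = 5,
                               min_covered_fraction = 0.8) {
  stopifnot(inherits(coverage, "CoverageTrack"),
            inherits(regions, "DifferentialRegions"))
  check_one <- function(intervals, cell_type) {
    if (nrow(intervals) == 0L)
      return(list(pass = TRUE, mean_depth = NA_real_,
                  covered_fraction = NA_real_))
    s <- coverage_stats(coverage, cell_type, regions$chrom, intervals)
    list(pass = s$mean_depth >= min_mean_depth &&
           s$covered_fraction >= min_covered_fraction,
         mean_depth = s$mean_depth, covered_fraction = s$covered_fraction)
  }
  r1 <- check_one(regions$unique_to_iso1, claim_iso1)
  r2 <- check_one(regions$unique_to_iso2, claim_iso2)
  list(iso1_pass = r1$pass, iso2_pass = r2$pass,
       rd_pass = r1$pass && r2$pass, iso1 = r1, iso2 = r2)
}

#' Relative isoform-support score and check (REL)
#'
#' Formalizes the relative-expression-level criterion: coverage in the
#' regions unique to each isoform, normalized by the shared-region
#' coverage of the same cell type, must switch direction between cell
#' types — evidence of a true isoform switch rather than an overall
#' expression difference. With unique-region means `u1(c)`, `u2(c)` and
#' shared mean `s(c)` per cell type `c` (each plus a pseudodepth),
#' the score is
#' `log2[(u1(soma)/s(soma)) / (u1(gonidia)/s(gonidia))] -
#'  log2[(u2(soma)/s(soma)) / (u2(gonidia)/s(gonidia))]`.
#' The check passes iff `|score| >= min_rel` and the two bracketed log2
#' terms have opposite signs; when one isoform has no unique region (it
#' is an exonic subset of the other, as with an internal start or an
#' extra terminal exon), its term is a null reference and the magnitude
#' criterion alone decides. A uniform depth scaling of one whole cell
#' type cancels in the normalization and leaves the score unchanged.
#'
#' @param coverage A [coverage_track()].
#' @param regions A [differential_regions()] result; an empty shared
#'   region makes the score undefined (`rel_pass = FALSE` with a
#'   reason).
#' @param min_rel Minimum |score| (log2 units).
#' @param pseudodepth Depth pseudocount added to every mean.
#' @return List with `rel_score`, `rel_pass`, the two per-isoform log2
#'   terms (`term_iso1`, `term_iso2`) and a `reason` string when
#'   undefined.
#' @export
relative_support_score <- function(coverage, regions, min_rel = 2,
                                   pseudodepth = 0.5) {
  stopifnot(inherits(coverage, "CoverageTrack"),
            inherits(regions, "DifferentialRegions"))
  if (nrow(regions$shared) == 0L)
    return(list(rel_score = NA_real_, rel_pass = FALSE,
                term_iso1 = NA_real_, term_iso2 = NA_real_,
                reason = "empty shared region"))
  m <- function(intervals, ct) {
    if (nrow(intervals) == 0L) return(pseudodepth)
    coverage_stats(coverage, ct, regions$chrom, intervals)$mean_depth +
      pseudodepth
  }
  u1s <- m(regions$unique_to_iso1, "soma")
  u1g <- m(regions$unique_to_iso1, "gonidia")
  u2s <- m(regions$unique_to_iso2, "soma")
  u2g <- m(regions$unique_to_iso2, "gonidia")
  ss <- m(regions$shared, "soma")
  sg <- m(regions$shared, "gonidia")
  t1 <- log2((u1s / ss) / (u1g / sg))
  t2 <- log2((u2s / ss) / (u2g / sg))
  score <- t1 - t2
  # the direction-switch requirement needs isoform-specific signal on
  # both sides; when one isoform is an exonic subset of the other (no
  # unique region), its term is a null reference and only the magnitude
  # criterion applies
  both_unique <- nrow(regions$unique_to_iso1) > 0L &&
    nrow(regions$unique_to_iso2) > 0L
  pass <- if (both_unique)
    abs(score) >= min_rel && sign(t1) * sign(t2) < 0
  else abs(score) >= min_rel
  list(rel_score = score, rel_pass = pass,
       term_iso1 = t1, term_iso2 = t2, reason = NA_character_)
}

# 3'-most exon of a transcript, honoring strand
three_prime_exon <- function(tx) {
  ex <- tx$exons
  if (tx$strand == "+") ex[nrow(ex), , drop = FALSE]
  else ex[1L, , drop = FALSE]
}

#' Detect convergent overlapping antisense gene pairs
#'
#' Finds pairs of distinct genes on opposite strands whose exonic spans
#' overlap by at least `min_overlap` bases at their 3' ends: the overlap
#' must intersect the 3'-most exon of both partners (overlapping 3'UTRs,
#' the geometry of convergent transcription). When per-gene expression
#' ratios are supplied, each pair is annotated with whether the partners
#' show opposite cell-type bias (one ER above `tau_bias`, the other
#' below its reciprocal).
#'
#' @param models Named list of [gene_model()] objects (strand-bearing).
#' @param gene_er Optional named numeric vector of gene-level
#'   soma/gonidia expression ratios.
#' @param min_overlap Minimum exonic overlap in bases.
#' @param tau_bias Bias cutoff used for `opposite_bias`.
#' @return Data frame with columns `gene_a`, `gene_b` (gene_a < gene_b),
#'   `overlap_bp`, `opposite_bias`.
#' @export
detect_convergent_pairs <- function(models, gene_er = NULL,
                                    min_overlap = 1L, tau_bias = 2) {
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      overlap_bp = integer(), opposite_bias = logical(),
                      stringsAsFactors = FALSE)
  if (length(models) < 2L) return(empty)
  spans <- lapply(models, function(gm) exonic_union(gm$transcripts))
  gr <- GenomicRanges::GRanges(
    vapply(models, `[[`, character(1), "chrom"),
    IRanges::IRanges(vapply(spans, function(s) min(IRanges::start(s)),
                            numeric(1)),
                     vapply(spans, function(s) max(IRanges::end(s)),
                            numeric(1))),
    strand = vapply(models, `[[`, character(1), "strand"))
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  hits <- hits[S4Vectors::queryHits(hits) < S4Vectors::subjectHits(hits)]
  rows <- list()
  for (k in seq_along(hits)) {
    i <- S4Vectors::queryHits(hits)[k]
    j <- S4Vectors::subjectHits(hits)[k]
    gm_i <- models[[i]]; gm_j <- models[[j]]
    if (gm_i$strand == gm_j$strand) next
    ov <- IRanges::intersect(spans[[i]], spans[[j]])
    if (sum(IRanges::width(ov)) < min_overlap) next
    # the overlap must reach the 3'-most exon of every transcript end;
    # use each gene's 3'-most exon across its transcripts
    ok <- TRUE
    for (gm in list(gm_i, gm_j)) {
      tp <- do.call(rbind, lapply(gm$transcripts, three_prime_exon))
      tp_ir <- exons_to_iranges(tp)
      if (sum(IRanges::width(IRanges::intersect(ov, tp_ir))) == 0L)
        ok <- FALSE
    }
    if (!ok) next
    ga <- sort(c(gm_i$gene_id, gm_j$gene_id))
    opp <- NA
    if (!is.null(gene_er) &&
        all(ga %in% names(gene_er))) {
      e1 <- gene_er[[ga[1L]]]; e2 <- gene_er[[ga[2L]]]
      opp <- (e1 > tau_bias && e2 < 1 / tau_bias) ||
        (e2 > tau_bias && e1 < 1 / tau_bias)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = ga[1L], gene_b = ga[2L],
      overlap_bp = sum(IRanges::width(ov)), opposite_bias = opp,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

# convergent-geometry flag for one candidate's own isoform pair: the two
# "isoforms" are on opposite strands and their exonic footprints overlap
# only at their mutual 3' ends — the signature of two adjacent genes
# fused into one locus by unstranded assembly
candidate_is_convergent <- function(iso1, iso2, min_overlap = 1L) {
  if (iso1$strand == iso2$strand) return(FALSE)
  a <- IRanges::reduce(exons_to_iranges(iso1$exons))
  b <- IRanges::reduce(exons_to_iranges(iso2$exons))
  ov <- IRanges::intersect(a, b)
  if (sum(IRanges::width(ov)) < min_overlap) return(FALSE)
  for (tx in list(iso1, iso2)) {
    tp <- exons_to_iranges(three_prime_exon(tx))
    if (sum(IRanges::width(IRanges::intersect(ov, tp))) == 0L)
      return(FALSE)
  }
  TRUE
}

#' Curate candidate genes with the RD, REL and convergent-pair screens
#'
#' Applies, in order, the read-density check (RD), the relative-support
#' check (REL), and the convergent-transcript screen (CT) to every
#' candidate record. A candidate is retained iff it passes RD and REL
#' and is not flagged convergent; the exclusion reason is the first
#' failing criterion in that order.
#'
#' @param records List of candidate records (see
#'   [apply_filter_cascade()]); only their gene ids and isoform ERs are
#'   used.
#' @param models Named list of [gene_model()] covering every candidate
#'   gene; two-isoform models are required.
#' @param coverage A [coverage_track()].
#' @param min_mean_depth,min_covered_fraction RD cutoffs.
#' @param min_rel,pseudodepth REL cutoffs.
#' @return List with `results` (data frame: gene_id, rd_pass, rel_pass,
#'   rel_score, convergent_flag, final) and `summary` (retained /
#'   excluded counts per reason).
#' @export
curate <- function(records, models, coverage,
                   min_mean_depth = 5, min_covered_fraction = 0.8,
                   min_rel = 2, pseudodepth = 0.5) {
  rows <- lapply(records, function(rec) {
    gm <- models[[rec$gene_id]]
    if (is.null(gm))
      stop("candidate gene ", rec$gene_id, " has no model")
    if (length(gm$transcripts) != 2L)
      stop("candidate gene ", rec$gene_id, " is not a two-isoform model")
    tids <- vapply(gm$transcripts, `[[`, character(1), "transcript_id")
    tx1 <- gm$transcripts[[match(rec$iso1$transcript_id, tids)]]
    tx2 <- gm$transcripts[[match(rec$iso2$transcript_id, tids)]]
    regions <- differential_regions(tx1, tx2)
    # iso1 is the higher-ER (soma-biased) isoform by record convention
    rd <- read_density_check(coverage, regions,
                             claim_iso1 = "soma", claim_iso2 = "gonidia",
                             min_mean_depth = min_mean_depth,
                             min_covered_fraction = min_covered_fraction)
    rel <- relative_support_score(coverage, regions, min_rel = min_rel,
                                  pseudodepth = pseudodepth)
    ct <- candidate_is_convergent(tx1, tx2)
    final <- if (!rd$rd_pass) "excluded_RD"
    else if (!rel$rel_pass) "excluded_REL"
    else if (ct) "excluded_CT"
    else "retained"
    data.frame(gene_id = rec$gene_id, rd_pass = rd$rd_pass,
               rel_pass = rel$rel_pass, rel_score = rel$rel_score,
               convergent_flag = ct, final = final,
               stringsAsFactors = FALSE)
  })
  results <- if (length(rows)) do.call(rbind, rows)
  else data.frame(gene_id = character(), rd_pass = logical(),
                  rel_pass = logical(), rel_score = numeric(),
                  convergent_flag = logical(), final = character(),
                  stringsAsFactors = FALSE)
  summary <- data.frame(
    n_input = nrow(results),
    retained = sum(results$final == "retained"),
    excluded_RD = sum(results$final == "excluded_RD"),
    excluded_REL = sum(results$final == "excluded_REL"),
    excluded_CT = sum(results$final == "excluded_CT"))
  list(results = results, summary = summary)
}
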