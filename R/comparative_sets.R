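#' Normalize gene identifiers before set operations
#'
#' Volvox annotations mix identifier styles across assembly versions
#' (e.g. `Vocar.0004s0224`, legacy `Vocar20012504m.g`), and transcript
#' ids carry numeric suffixes (`.1`, `.2`). The rule applied here:
#' trim whitespace, drop one trailing all-digit dot-component
#' (transcript / version suffix), and drop a legacy trailing `.g`
#' following an `m` model suffix. Locus components like `0004s0224`
#' contain letters and are never stripped.
#'
#' @param ids Character vector of gene or transcript identifiers.
#' @return Character vector of normalized gene identifiers.
#' @export
normalize_gene_ids <- function(ids) {
  ids <- trimws(ids)
  ids <- sub("\\.[0-9]+$", "", ids)   # transcript/version suffix
  ids <- sub("(m)\\.g$", "\\1", ids)  # legacy "m.g" gene form
  ids
}

#' Construct a labeled gene set
#'
#' @param label Set label (e.g. the annotation source).
#' @param ids Gene identifiers; normalized via [normalize_gene_ids()]
#'   unless `normalize = FALSE`, then de-duplicated (set semantics).
#' @param normalize Apply identifier normalization.
#' @return An object of class `GeneSet` with fields `label`, `ids`.
#' @export
gene_set <- function(label, ids, normalize = TRUE) {
  if (normalize) ids <- normalize_gene_ids(ids)
  structure(list(label = label, ids = unique(as.character(ids))),
            class = "GeneSet")
}

#' Merge two candidate gene sets with provenance
#'
#' Exact set union; every merged gene is tagged with its provenance
#' (first set only, second set only, or both). The overlap report
#' satisfies inclusion-exclusion by construction.
#'
#' @param a,b [gene_set()] objects.
#' @return List with `report` (data frame: size_a, size_b, intersection,
#'   union, unique_a, unique_b) and `merged` (data frame: gene_id,
#'   provenance in `{a_only, b_only, both}`), sorted by gene_id.
#' @export
merge_candidate_sets <- function(a, b) {
  stopifnot(inherits(a, "GeneSet"), inherits(b, "GeneSet"))
  inter <- intersect(a$ids, b$ids)
  uni <- union(a$ids, b$ids)
  provenance <- ifelse(uni %in% inter, "both",
                       ifelse(uni %in% a$ids, "a_only", "b_only"))
  merged <- data.frame(gene_id = uni, provenance = provenance,
                       stringsAsFactors = FALSE)
  merged <- merged[order(merged$gene_id), , drop = FALSE]
  rownames(merged) <- NULL
  list(report = data.frame(size_a = length(a$ids), size_b = length(b$ids),
                           intersection = length(inter),
                           union = length(uni),
                           unique_a = length(a$ids) - length(inter),
                           unique_b = length(b$ids) - length(inter)),
       merged = merged)
}

#' Cross-species alternative-splicing conservation overlap
#'
#' Given a 1:1 ortholog map between species A and B and, per species,
#' the set of genes with alternative isoforms, counts the ortholog pairs
#' whose A-member is alternatively spliced, whose B-member is, and whose
#' both members are (conserved alternative splicing).
#'
#' @param orthologs Data frame from [read_ortholog_map()] (columns
#'   `gene_a`, `gene_b`).
#' @param as_genes_a,as_genes_b [gene_set()] objects of alternatively
#'   spliced genes in species A and B.
#' @return Data frame with one row: `pairs_in_map_a`, `pairs_in_map_b`,
#'   `pairs_both`.
#' @export
as_conservation_overlap <- function(orthologs, as_genes_a, as_genes_b) {
  stopifnot(inherits(as_genes_a, "GeneSet"), inherits(as_genes_b, "GeneSet"))
  in_a <- normalize_gene_ids(orthologs$gene_a) %in% as_genes_a$ids
  in_b <- normalize_gene_ids(orthologs$gene_b) %in% as_genes_b$ids
  data.frame(pairs_in_map_a = sum(in_a),
             pairs_in_map_b = sum(in_b),
             pairs_both = sum(in_a & in_b))
}
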