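#' Default PFAM accessions defining RNA-binding-protein genes
#'
#' RNA recognition motif (PF00076), KH domain (PF00013), G-patch domain
#' (PF01585) and the two DEAD/helicase-family RNA helicase domains
#' (PF00270, PF00271). Extensible via the `rbp_pfams` argument of
#' [identify_rbp_genes()].
#'
#' @export
default_rbp_pfams <- c("PF00076", "PF00013", "PF01585", "PF00270",
                       "PF00271")

#' Identify RNA-binding-protein genes by PFAM domain content
#'
#' @param domains Data frame from [read_domain_table()] (columns
#'   `gene_id`, `pfam`).
#' @param rbp_pfams Character vector of qualifying PFAM accessions.
#' @return A [gene_set()] (label `"rbp"`) of genes carrying at least one
#'   listed domain.
#' @export
identify_rbp_genes <- function(domains, rbp_pfams = default_rbp_pfams) {
  gene_set("rbp", sort(unique(domains$gene_id[domains$pfam %in% rbp_pfams])),
           normalize = FALSE)
}

#' Classify RNA-binding-protein genes by cell-type expression bias
#'
#' Gene-level FPKM (transcript sum per sample) yields a soma/gonidia
#' expression ratio per gene; the fold bias `max(ER, 1/ER)` places each
#' gene in one of three tiers: `similar` (fold < 2), `modest`
#' (2 <= fold <= 5) or `specific` (fold > 5, cell-type-specific). The
#' direction is soma for ER > 1 and gonidia for ER < 1 (none for the
#' similar tier). Boundary folds of exactly 2 and 5 fall in the modest
#' tier.
#'
#' @param table An [expression_table()].
#' @param rbps A [gene_set()] of RNA-binding-protein genes; genes absent
#'   from the expression table are dropped.
#' @param pseudocount FPKM pseudocount for the ratio.
#' @return List with `records` (data frame: gene_id, ER, fold, category,
#'   direction) and `counts` (data frame of gene counts per category and
#'   direction).
#' @export
classify_rbp_bias <- function(table, rbps, pseudocount = 0.01) {
  stopifnot(inherits(table, "ExpressionTable"), inherits(rbps, "GeneSet"))
  g <- gene_fpkm(table)
  ids <- sort(intersect(rbps$ids, rownames(g)))
  soma_cols <- samples_of(table$design, "soma")
  gon_cols <- samples_of(table$design, "gonidia")
  ms <- rowMeans(g[ids, soma_cols, drop = FALSE])
  mg <- rowMeans(g[ids, gon_cols, drop = FALSE])
  er <- (ms + pseudocount) / (mg + pseudocount)
  fold <- pmax(er, 1 / er)
  category <- ifelse(fold < 2, "similar",
                     ifelse(fold > 5, "specific", "modest"))
  direction <- ifelse(category == "similar", "none",
                      ifelse(er > 1, "soma", "gonidia"))
  records <- data.frame(gene_id = ids, ER = unname(er),
                        fold = unname(fold), category = category,
                        direction = direction, stringsAsFactors = FALSE)
  counts <- as.data.frame(base::table(category = records$category,
                                      direction = records$direction),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0, , drop = FALSE]
  rownames(counts) <- NULL
  list(records = records, counts = counts)
}
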