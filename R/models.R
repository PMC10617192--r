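#' @importFrom methods is
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- Rle runValue
NULL

# Internal coordinate convention: all exon intervals are 0-based half-open
# [start, end). Conversion to/from 1-based inclusive happens only at the
# GFF3 / IRanges boundary (see exons_to_iranges / iranges_to_exons).

#' Construct a transcript model
#'
#' A transcript model holds the exon structure of a single transcript
#' isoform: its identifiers, chromosome, strand and an ordered set of
#' non-overlapping exon intervals in 0-based half-open coordinates.
#'
#' @param transcript_id Character scalar, unique transcript identifier.
#' @param gene_id Character scalar, identifier of the parent gene.
#' @param chrom Character scalar, chromosome/scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column numeric matrix of exon intervals
#'   (columns `start`, `end`; 0-based half-open). Rows are sorted by start
#'   and must not overlap.
#' @param source Annotation source tag: `"ballgown"`, `"phytozome"` or
#'   `"synthetic"`.
#' @return An object of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             source = "synthetic") {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(gene_id), length(gene_id) == 1L,
            is.character(chrom), length(chrom) == 1L)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-' for transcript ", transcript_id)
  exons <- as.matrix(exons)
  if (nrow(exons) == 0L)
    stop("transcript ", transcript_id, " has no exons")
  if (ncol(exons) != 2L)
    stop("exons must be a two-column (start, end) matrix")
  storage.mode(exons) <- "double"
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("transcript ", transcript_id, ": exon with end <= start")
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("transcript ", transcript_id, ": overlapping exons")
  colnames(exons) <- c("start", "end")
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 source = source),
            class = "TranscriptModel")
}

#' Construct a gene model
#'
#' @param gene_id Character scalar.
#' @param transcripts List of [transcript_model()] objects; all must share
#'   `gene_id` and chromosome.
#' @return An object of class `GeneModel` with fields `gene_id`, `chrom`,
#'   `strand` and `transcripts`.
#' @export
gene_model <- function(gene_id, transcripts) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            is.list(transcripts), length(transcripts) >= 1L)
  if (!all(vapply(transcripts, inherits, logical(1), "TranscriptModel")))
    stop("transcripts must all be TranscriptModel objects")
  gids <- vapply(transcripts, `[[`, character(1), "gene_id")
  if (!all(gids == gene_id))
    stop("gene ", gene_id, ": transcript with mismatching gene_id")
  chroms <- unique(vapply(transcripts, `[[`, character(1), "chrom"))
  if (length(chroms) != 1L)
    stop("gene ", gene_id, ": transcripts on multiple chromosomes")
  structure(list(gene_id = gene_id, chrom = chroms,
                 strand = transcripts[[1L]]$strand,
                 transcripts = transcripts),
            class = "GeneModel")
}

#' Construct a sample design
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param cell_type Character vector, each `"soma"` or `"gonidia"`.
#' @param replicate Positive integer vector of replicate indices.
#' @return A `SampleDesign` data frame with one row per sample.
#' @export
sample_design <- function(sample_id, cell_type, replicate) {
  stopifnot(length(sample_id) == length(cell_type),
            length(sample_id) == length(replicate))
  if (anyDuplicated(sample_id))
    stop("sample_ids must be unique")
  if (!all(cell_type %in% c("soma", "gonidia")))
    stop("cell_type must be 'soma' or 'gonidia'")
  if (!all(replicate >= 1 & replicate == as.integer(replicate)))
    stop("replicate must be a positive integer")
  if (!all(c("soma", "gonidia") %in% cell_type))
    stop("design needs at least one sample of each cell type")
  structure(data.frame(sample_id = as.character(sample_id),
                       cell_type = as.character(cell_type),
                       replicate = as.integer(replicate),
                       stringsAsFactors = FALSE),
            class = c("SampleDesign", "data.frame"))
}

#' Construct an expression table
#'
#' Transcript-by-sample FPKM matrix together with the transcript-to-gene
#' mapping and the sample design. All values must be finite and
#' non-negative; columns are aligned to the design order.
#'
#' @param fpkm Numeric matrix, rows named by transcript_id, columns named
#'   by sample_id.
#' @param tx2gene Named character vector mapping transcript_id to gene_id;
#'   names must cover the rownames of `fpkm`.
#' @param design A [sample_design()].
#' @return An object of class `ExpressionTable`.
#' @export
expression_table <- function(fpkm, tx2gene, design) {
  stopifnot(is.matrix(fpkm), inherits(design, "SampleDesign"))
  if (is.null(rownames(fpkm)) || is.null(colnames(fpkm)))
    stop("fpkm matrix must have transcript rownames and sample colnames")
  if (!setequal(colnames(fpkm), design$sample_id))
    stop("design mismatch: fpkm columns {",
         paste(colnames(fpkm), collapse = ", "),
         "} do not equal design samples {",
         paste(design$sample_id, collapse = ", "), "}")
  fpkm <- fpkm[, design$sample_id, drop = FALSE]
  if (any(!is.finite(fpkm)))
    stop("FPKM values must be finite (no missing values)")
  if (any(fpkm < 0))
    stop("negative FPKM value encountered")
  missing_tx <- setdiff(rownames(fpkm), names(tx2gene))
  if (length(missing_tx))
    stop("transcripts without gene mapping: ",
         paste(utils::head(missing_tx, 5), collapse = ", "))
  structure(list(fpkm = fpkm,
                 tx2gene = tx2gene[rownames(fpkm)],
                 design = design),
            class = "ExpressionTable")
}

# --- small shared helpers ---------------------------------------------------

# 0-based half-open exon matrix -> IRanges (1-based inclusive)
exons_to_iranges <- function(exons) {
  IRanges::IRanges(start = exons[, 1L] + 1L, end = exons[, 2L])
}

# IRanges -> 0-based half-open matrix, sorted
iranges_to_exons <- function(ir) {
  ir <- IRanges::reduce(ir)  # reduce() output is sorted and disjoint
  cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# exonic union of a transcript list as reduced IRanges
exonic_union <- function(transcripts) {
  IRanges::reduce(do.call(c, lapply(transcripts, function(tx)
    exons_to_iranges(tx$exons))))
}

# flatten a list of GeneModel into a data.frame of transcripts
transcript_index <- function(models) {
  rows <- lapply(models, function(gm) {
    data.frame(gene_id = gm$gene_id,
               transcript_id = vapply(gm$transcripts, `[[`, character(1),
                                      "transcript_id"),
               chrom = gm$chrom, strand = gm$strand,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# samples of one cell type
samples_of <- function(design, cell_type) {
  design$sample_id[design$cell_type == cell_type]
}

#' Gene-level FPKM: sum transcript FPKM per gene and sample
#'
#' @param table An [expression_table()].
#' @return Numeric matrix, genes x samples.
#' @export
gene_fpkm <- function(table) {
  stopifnot(inherits(table, "ExpressionTable"))
  rowsum(table$fpkm, group = table$tx2gene[rownames(table$fpkm)])
}
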