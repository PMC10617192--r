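#' Read gene models from a GFF3 file
#'
#' Parses a GFF3 annotation with gene / mRNA (or transcript) / exon
#' features linked by `ID`/`Parent` attributes. GFF3 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention
#' at this boundary.
#'
#' @param path Path to a GFF3 file.
#' @param source Source tag stored on every transcript
#'   (`"ballgown"`, `"phytozome"` or `"synthetic"`).
#' @return Named list of [gene_model()] objects, keyed by gene_id.
#' @export
read_gff3 <- function(path, source = "phytozome") {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))

  genes <- gr[type == "gene"]
  txs <- gr[type %in% c("mRNA", "transcript")]
  exons <- gr[type == "exon"]

  tx_ids <- ids[type %in% c("mRNA", "transcript")]
  tx_parents <- parents[type %in% c("mRNA", "transcript")]
  gene_ids <- ids[type == "gene"]
  if (anyNA(tx_ids) || anyNA(tx_parents))
    stop("GFF3 parse error: mRNA/transcript feature without ID or Parent")
  bad <- setdiff(tx_parents, gene_ids)
  if (length(bad))
    stop("GFF3 parse error: transcript Parent not a gene feature: ",
         paste(utils::head(bad, 5), collapse = ", "))

  exon_parents <- parents[type == "exon"]
  if (anyNA(exon_parents))
    stop("GFF3 parse error: exon without Parent transcript")
  bad <- setdiff(exon_parents, tx_ids)
  if (length(bad))
    stop("GFF3 parse error: exon Parent not an mRNA/transcript feature: ",
         paste(utils::head(bad, 5), collapse = ", "))

  exon_by_tx <- split(seq_along(exons), exon_parents)
  tx_models <- lapply(seq_along(txs), function(i) {
    tid <- tx_ids[i]
    idx <- exon_by_tx[[tid]]
    if (is.null(idx))
      stop("GFF3 parse error: transcript ", tid, " has no exon features")
    ex <- exons[idx]
    # 1-based inclusive -> 0-based half-open
    m <- cbind(start = GenomicRanges::start(ex) - 1L,
               end = GenomicRanges::end(ex))
    transcript_model(tid, tx_parents[i],
                     as.character(GenomicRanges::seqnames(ex))[1L],
                     as.character(GenomicRanges::strand(txs[i])),
                     m, source = source)
  })
  names(tx_models) <- tx_ids

  models <- lapply(gene_ids, function(gid) {
    child <- tx_models[tx_parents == gid]
    if (!length(child))
      stop("GFF3 parse error: gene ", gid, " has no transcripts")
    gene_model(gid, unname(child))
  })
  names(models) <- gene_ids
  models
}

#' Write gene models to a GFF3 file
#'
#' Inverse of [read_gff3()]; internal 0-based half-open exon intervals are
#' converted back to GFF3 1-based inclusive coordinates.
#'
#' @param models Named list of [gene_model()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  rows <- list()
  for (gm in models) {
    span <- range(exonic_union(gm$transcripts))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = gm$chrom, start = IRanges::start(span), end = IRanges::end(span),
      strand = gm$strand, type = "gene", id = gm$gene_id,
      parent = NA_character_, stringsAsFactors = FALSE)
    for (tx in gm$transcripts) {
      ir <- exons_to_iranges(tx$exons)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tx$chrom, start = min(IRanges::start(ir)),
        end = max(IRanges::end(ir)), strand = tx$strand, type = "mRNA",
        id = tx$transcript_id, parent = gm$gene_id,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tx$chrom, start = IRanges::start(ir), end = IRanges::end(ir),
        strand = tx$strand, type = "exon", id = NA_character_,
        parent = tx$transcript_id, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$type <- df$type
  gr$ID <- df$id
  gr$Parent <- ifelse(is.na(df$parent), "", df$parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a canonical expression TSV
#'
#' The canonical dialect is a tab-separated table with header columns
#' `transcript_id`, `gene_id`, then one FPKM column per sample in the
#' design. This is a reduction of a Ballgown `t_data.ctab` table: `t_name`
#' maps to `transcript_id`, `gene_id` to `gene_id`, and the per-sample
#' `FPKM.<sample>` columns to the design's sample columns; all other ctab
#' columns (coordinates, lengths, coverage) are carried by the gene models
#' instead.
#'
#' @param path Path to the TSV.
#' @param design A [sample_design()]; its sample set must equal the FPKM
#'   columns of the file.
#' @return An [expression_table()].
#' @export
read_expression_tsv <- function(path, design) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "gene_id") %in% colnames(df)))
    stop("expression TSV must have transcript_id and gene_id columns")
  value_cols <- setdiff(colnames(df), c("transcript_id", "gene_id"))
  if (!setequal(value_cols, design$sample_id))
    stop("design mismatch: file samples {",
         paste(value_cols, collapse = ", "), "} vs design {",
         paste(design$sample_id, collapse = ", "), "}")
  m <- as.matrix(df[, design$sample_id, drop = FALSE])
  if (!is.numeric(m) || anyNA(m))
    stop("expression TSV contains missing or non-numeric FPKM values")
  rownames(m) <- df$transcript_id
  expression_table(m, stats::setNames(df$gene_id, df$transcript_id), design)
}

#' Write an expression table to the canonical TSV dialect
#'
#' @param table An [expression_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(table, path) {
  df <- data.frame(transcript_id = rownames(table$fpkm),
                   gene_id = unname(table$tx2gene[rownames(table$fpkm)]),
                   table$fpkm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column TSV as a 1:1 ortholog map
#'
#' @param path Two-column tab-separated file (optional `#`-prefixed
#'   header), one ortholog pair per row.
#' @return Data frame with columns `gene_a`, `gene_b`. Any gene appearing
#'   in more than one pair is an error (1:1 invariant).
#' @export
read_ortholog_map <- function(path) {
  df <- read_two_col(path, c("gene_a", "gene_b"))
  df <- unique(df)
  if (anyDuplicated(df$gene_a) || anyDuplicated(df$gene_b))
    stop("ortholog map is not 1:1: gene appears in more than one pair")
  df
}

#' Read a two-column TSV as a gene-to-PFAM domain table
#'
#' @param path Two-column tab-separated file: gene_id, PFAM accession
#'   (`PFxxxxx`). Duplicate rows collapse under set semantics.
#' @return Data frame with columns `gene_id`, `pfam`.
#' @export
read_domain_table <- function(path) {
  df <- unique(read_two_col(path, c("gene_id", "pfam")))
  if (!all(grepl("^PF[0-9]{5}$", df$pfam)))
    stop("malformed PFAM accession: ",
         paste(utils::head(df$pfam[!grepl("^PF[0-9]{5}$", df$pfam)], 5),
               collapse = ", "))
  df
}

read_two_col <- function(path, col_names) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(stats::setNames(data.frame(character(), character(),
                                      stringsAsFactors = FALSE), col_names))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("expected two tab-separated columns in ", path)
  stats::setNames(data.frame(vapply(parts, `[[`, character(1), 1L),
                             vapply(parts, `[[`, character(1), 2L),
                             stringsAsFactors = FALSE), col_names)
}

#' Construct a per-base coverage track
#'
#' @param by_cell_type Named list (`soma`, `gonidia`) of
#'   [IRanges::RleList] objects giving per-base depth per chromosome.
#' @return An object of class `CoverageTrack`.
#' @export
coverage_track <- function(by_cell_type) {
  stopifnot(all(c("soma", "gonidia") %in% names(by_cell_type)))
  for (ct in names(by_cell_type)) {
    if (any(vapply(by_cell_type[[ct]], function(r) any(S4Vectors::runValue(r) < 0),
                   logical(1))))
      stop("negative depth in coverage track for ", ct)
  }
  structure(by_cell_type, class = "CoverageTrack")
}

#' Read coverage tracks from bedGraph files
#'
#' bedGraph intervals (0-based half-open, unstranded) are expanded lazily
#' into per-base run-length encoded depth vectors.
#'
#' @param paths Named character vector with elements `soma` and `gonidia`,
#'   each a bedGraph file path.
#' @return A [coverage_track()].
#' @export
read_coverage_bedgraph <- function(paths) {
  stopifnot(all(c("soma", "gonidia") %in% names(paths)))
  tracks <- lapply(paths[c("soma", "gonidia")], function(p) {
    gr <- rtracklayer::import(p, format = "bedGraph")
    GenomicRanges::coverage(gr, weight = gr$score)
  })
  coverage_track(tracks)
}

#' Write a coverage track to bedGraph files
#'
#' @param track A [coverage_track()].
#' @param prefix Output path prefix; files `<prefix>.soma.bedgraph` and
#'   `<prefix>.gonidia.bedgraph` are written.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_coverage_bedgraph <- function(track, prefix) {
  stopifnot(inherits(track, "CoverageTrack"))
  out <- c(soma = paste0(prefix, ".soma.bedgraph"),
           gonidia = paste0(prefix, ".gonidia.bedgraph"))
  for (ct in names(out)) {
    gr <- GenomicRanges::GRanges(track[[ct]])
    gr <- gr[gr$score != 0]
    rtracklayer::export(gr, out[[ct]], format = "bedGraph")
  }
  invisible(out)
}

# mean depth and covered fraction over 0-based half-open intervals
coverage_stats <- function(track, cell_type, chrom, intervals) {
  rl <- track[[cell_type]]
  if (!chrom %in% names(rl))
    stop("coverage track has no chromosome ", chrom, " for ", cell_type)
  r <- rl[[chrom]]
  if (nrow(intervals) == 0L)
    return(list(mean_depth = NA_real_, covered_fraction = NA_real_,
                n_bases = 0L))
  if (max(intervals[, 2L]) > length(r))
    stop("query interval extends beyond coverage on ", chrom)
  v <- IRanges::Views(r, start = intervals[, 1L] + 1L, end = intervals[, 2L])
  widths <- intervals[, 2L] - intervals[, 1L]
  total <- sum(widths)
  list(mean_depth = sum(IRanges::viewSums(v)) / total,
       covered_fraction =
         sum(vapply(seq_along(v), function(i)
           sum(as.numeric(v[[i]]) > 0), numeric(1))) / total,
       n_bases = total)
}

#' Write the candidate report TSV
#'
#' One row per gene with per-isoform means, expression ratios, p-values,
#' the combined bias B, the aggregate p-value, per-stage pass flags and
#' the final verdict. Rows are ordered by gene_id so repeated writes are
#' byte-identical; non-applicable fields are written as `"."`.
#'
#' @param records List of candidate records from [run_detection()] /
#'   [apply_filter_cascade()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(records, path) {
  df <- candidate_table(records)
  df <- df[order(df$gene_id), , drop = FALSE]
  out <- as.data.frame(lapply(df, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- "."
    col
  }), stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Flatten candidate records into a data frame
#'
#' @param records List of `CandidateRecord` objects.
#' @return Data frame with one row per record.
#' @export
candidate_table <- function(records) {
  cols <- c("gene_id", "source",
            "iso1_id", "iso1_mean_soma", "iso1_mean_gonidia", "iso1_ER",
            "iso1_log2ER", "iso1_p",
            "iso2_id", "iso2_mean_soma", "iso2_mean_gonidia", "iso2_ER",
            "iso2_log2ER", "iso2_p",
            "B", "aggregate_p",
            "passed_stage1", "passed_stage2", "passed_stage3", "verdict")
  if (!length(records)) {
    df <- as.data.frame(stats::setNames(rep(list(character()), length(cols)),
                                        cols), stringsAsFactors = FALSE)
    return(df)
  }
  rows <- lapply(records, function(r) {
    data.frame(gene_id = r$gene_id, source = r$source,
               iso1_id = r$iso1$transcript_id,
               iso1_mean_soma = r$iso1$mean_soma,
               iso1_mean_gonidia = r$iso1$mean_gonidia,
               iso1_ER = r$iso1$ER, iso1_log2ER = r$iso1$log2ER,
               iso1_p = r$iso1$p_value,
               iso2_id = r$iso2$transcript_id,
               iso2_mean_soma = r$iso2$mean_soma,
               iso2_mean_gonidia = r$iso2$mean_gonidia,
               iso2_ER = r$iso2$ER, iso2_log2ER = r$iso2$log2ER,
               iso2_p = r$iso2$p_value,
               B = r$B, aggregate_p = r$aggregate_p,
               passed_stage1 = r$passed_stage1,
               passed_stage2 = r$passed_stage2,
               passed_stage3 = r$passed_stage3,
               verdict = r$verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
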