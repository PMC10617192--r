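# shared fixture builders and independent oracles

make_design <- function(n_rep = 2L) {
  sample_design(
    sample_id = c(paste0("s", seq_len(n_rep)), paste0("g", seq_len(n_rep))),
    cell_type = rep(c("soma", "gonidia"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2L))
}

# expression table from a named list transcript_id -> c(soma..., gonidia...)
make_table <- function(values, tx2gene, n_rep = 2L) {
  design <- make_design(n_rep)
  m <- do.call(rbind, values)
  rownames(m) <- names(values)
  colnames(m) <- design$sample_id
  expression_table(m, tx2gene, design)
}

# single-chromosome gene model with one transcript per exon matrix given
make_gene <- function(gene_id, exon_sets, strand = "+", chrom = "chrT") {
  txs <- lapply(seq_along(exon_sets), function(i)
    transcript_model(sprintf("%s.%d", gene_id, i), gene_id, chrom,
                     strand, exon_sets[[i]]))
  gene_model(gene_id, txs)
}

ivl <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

# coverage track from per-cell-type depth step functions
make_coverage <- function(soma_values, soma_lengths,
                          gonidia_values, gonidia_lengths,
                          chrom = "chrT") {
  mk <- function(v, l) {
    rl <- IRanges::RleList(S4Vectors::Rle(v, l))
    names(rl) <- chrom
    rl
  }
  coverage_track(list(soma = mk(soma_values, soma_lengths),
                      gonidia = mk(gonidia_values, gonidia_lengths)))
}

# --- independent oracles ----------------------------------------------------

# textbook pooled-variance two-sided t-test on log2(FPKM + 1)
oracle_pooled_t <- function(soma, gonidia) {
  x <- log2(soma + 1); y <- log2(gonidia + 1)
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * stats::pt(-abs(tstat), df = nx + ny - 2)
}

# expand a 0-based half-open interval matrix to its base set
intervals_to_bases <- function(m) {
  if (nrow(m) == 0L) return(integer())
  unlist(lapply(seq_len(nrow(m)), function(i) seq(m[i, 1L], m[i, 2L] - 1L)))
}

# brute-force per-base differential regions of two exon matrices
oracle_differential_bases <- function(ex1, ex2) {
  a <- intervals_to_bases(ex1); b <- intervals_to_bases(ex2)
  list(unique1 = sort(setdiff(a, b)), unique2 = sort(setdiff(b, a)),
       shared = sort(intersect(a, b)))
}

# random non-overlapping sorted exon matrix
random_exons <- function(max_exons = 4L, span = 400L) {
  n <- sample.int(max_exons, 1L)
  bounds <- sort(sample.int(span, 2L * n))
  m <- matrix(bounds, ncol = 2L, byrow = TRUE)
  keep <- m[, 2L] > m[, 1L]
  if (!any(keep)) return(random_exons(max_exons, span))
  m <- m[keep, , drop = FALSE]
  colnames(m) <- c("start", "end")
  m
}
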