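#' Simulation parameters for the synthetic dataset generator
#'
#' The generator emulates the statistical structure of a two-cell-type
#' (soma vs gonidia) transcript-level FPKM experiment: log-normal baseline
#' expression, multiplicative log-normal replicate noise, genes with one
#' to K isoforms, planted genes whose two isoforms carry opposite
#' cell-type biases, and planted adjacent convergent gene pairs whose
#' 3'-most exons overlap.
#'
#' @param n_genes Total genes to simulate.
#' @param isoform_count_distribution Probability vector over isoform
#'   counts 1..K for null genes; defaults follow the roughly 0.89 / 0.09 /
#'   0.02 split of single / double / higher isoform counts seen in
#'   transcript assemblies of the Volvox transcriptome.
#' @param n_ctsai Number of planted cell-type-specific alternative
#'   isoform (CTSAI) genes; each gets exactly two isoforms with opposite
#'   biases.
#' @param n_convergent_pairs Number of planted convergent overlapping
#'   gene pairs (each consumes two genes).
#' @param effect_log2 Planted per-isoform |log2 expression-ratio|
#'   magnitude; an isoform with bias `b` has soma mean `mu * 2^b` and
#'   gonidia mean `mu * 2^-b`.
#' @param baseline_fpkm_log_mean,baseline_fpkm_log_sd Parameters of the
#'   log-normal baseline FPKM distribution (natural-log scale).
#' @param replicate_cv Coefficient of variation of the multiplicative
#'   log-normal replicate noise; 0 gives exactly identical replicates.
#' @param replicates_per_cell_type Replicates per cell type (>= 2).
#' @param convergent_overlap_bp Bases by which the 3'-most exons of a
#'   planted convergent pair overlap.
#' @param seed Integer RNG seed; all generators are deterministic given
#'   the seed.
#' @return An object of class `SimulationParams`.
#' @export
simulation_params <- function(n_genes = 200L,
                              isoform_count_distribution = c(0.888, 0.088, 0.024),
                              n_ctsai = 20L,
                              n_convergent_pairs = 4L,
                              effect_log2 = 2,
                              baseline_fpkm_log_mean = log(20),
                              baseline_fpkm_log_sd = 1,
                              replicate_cv = 0.2,
                              replicates_per_cell_type = 4L,
                              convergent_overlap_bp = 50L,
                              seed = 1L) {
  p <- isoform_count_distribution
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
    stop("isoform_count_distribution must be a probability vector")
  if (n_ctsai + 2L * n_convergent_pairs > n_genes)
    stop("planted genes exceed n_genes")
  if (effect_log2 < 0) stop("effect_log2 must be >= 0")
  if (replicate_cv < 0) stop("replicate_cv must be >= 0")
  if (replicates_per_cell_type < 2L)
    stop("need >= 2 replicates per cell type")
  structure(list(n_genes = as.integer(n_genes),
                 isoform_count_distribution = p,
                 n_ctsai = as.integer(n_ctsai),
                 n_convergent_pairs = as.integer(n_convergent_pairs),
                 effect_log2 = effect_log2,
                 baseline_fpkm_log_mean = baseline_fpkm_log_mean,
                 baseline_fpkm_log_sd = baseline_fpkm_log_sd,
                 replicate_cv = replicate_cv,
                 replicates_per_cell_type = as.integer(replicates_per_cell_type),
                 convergent_overlap_bp = as.integer(convergent_overlap_bp),
                 seed = as.integer(seed)),
            class = "SimulationParams")
}

# run expr with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# the three planted two-isoform architectures: the second isoform gains an
# extra 3' exon, uses an alternative first exon, or starts internally
ctsai_architectures <- c("extra_3prime_exon", "alt_first_exon",
                         "internal_start")

# build the exon matrices for a two-isoform gene at genomic offset `at`
two_isoform_exons <- function(at, architecture, exon_w = 200L, intron_w = 100L) {
  base <- cbind(start = at + (0:3) * (exon_w + intron_w))
  base <- cbind(base, end = base[, 1L] + exon_w)
  iso2 <- switch(architecture,
    extra_3prime_exon = {
      extra <- base[4L, 2L] + intron_w
      rbind(base, c(extra, extra + exon_w))
    },
    alt_first_exon = {
      alt <- base[1L, , drop = FALSE] + intron_w %/% 2L
      alt[1L, 2L] <- base[2L, 1L] - 10L  # keep it clear of exon 2
      rbind(alt, base[-1L, , drop = FALSE])
    },
    internal_start = base[-1L, , drop = FALSE],
    stop("unknown architecture ", architecture))
  colnames(iso2) <- c("start", "end")
  list(iso1 = base, iso2 = iso2)
}

#' Generate a synthetic annotation with planted ground truth
#'
#' Genes are laid out left to right on one synthetic chromosome with
#' fixed intergenic spacing. Planted CTSAI genes get exactly two isoforms
#' differing by at least one exon, cycling through three architectures
#' (extra 3' exon, alternative first exon, internal start). Planted
#' convergent pairs are adjacent genes on opposite strands whose 3'-most
#' exons overlap by `convergent_overlap_bp`.
#'
#' @param params A [simulation_params()].
#' @return List with `models` (named list of [gene_model()]), `truth`
#'   (data frame `gene_id`, `label` with labels `ctsai`,
#'   `convergent_partner_soma`, `convergent_partner_gonidia`,
#'   `null_single_isoform`, `null_multi_isoform`), and `chrom_length`.
#' @export
generate_annotation <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  with_local_seed(params$seed, {
    n_null <- params$n_genes - params$n_ctsai - 2L * params$n_convergent_pairs
    # layout units: a convergent pair occupies one unit of two genes
    units <- c(rep("ctsai", params$n_ctsai),
               rep("convergent_pair", params$n_convergent_pairs),
               rep("null", n_null))
    units <- sample(units)
    k_choices <- seq_along(params$isoform_count_distribution)
    null_k <- sample(k_choices, n_null, replace = TRUE,
                     prob = params$isoform_count_distribution)

    exon_w <- 200L; intron_w <- 100L; spacing <- 500L
    chrom <- "chrS"
    models <- list(); truth <- list()
    at <- spacing
    gi <- 0L; ni <- 0L; arch_i <- 0L
    for (u in units) {
      if (u == "ctsai") {
        gi <- gi + 1L; arch_i <- arch_i + 1L
        gid <- sprintf("gene%04d", gi)
        arch <- ctsai_architectures[(arch_i - 1L) %%
                                      length(ctsai_architectures) + 1L]
        ex <- two_isoform_exons(at, arch, exon_w, intron_w)
        txs <- list(
          transcript_model(paste0(gid, ".1"), gid, chrom, "+", ex$iso1),
          transcript_model(paste0(gid, ".2"), gid, chrom, "+", ex$iso2))
        models[[gid]] <- gene_model(gid, txs)
        truth[[gid]] <- "ctsai"
        at <- max(ex$iso1[, 2L], ex$iso2[, 2L]) + spacing
      } else if (u == "convergent_pair") {
        gi <- gi + 2L
        gid_a <- sprintf("gene%04d", gi - 1L)
        gid_b <- sprintf("gene%04d", gi)
        # partner A: + strand, 3 exons; partner B: - strand, 3 exons,
        # B's leftmost (3'-most) exon overlaps A's rightmost (3'-most)
        a <- cbind(start = at + (0:2) * (exon_w + intron_w))
        a <- cbind(a, end = a[, 1L] + exon_w)
        b_start <- a[3L, 2L] - params$convergent_overlap_bp
        b <- cbind(start = b_start + (0:2) * (exon_w + intron_w))
        b <- cbind(b, end = b[, 1L] + exon_w)
        colnames(a) <- colnames(b) <- c("start", "end")
        models[[gid_a]] <- gene_model(gid_a, list(
          transcript_model(paste0(gid_a, ".1"), gid_a, chrom, "+", a)))
        models[[gid_b]] <- gene_model(gid_b, list(
          transcript_model(paste0(gid_b, ".1"), gid_b, chrom, "-", b)))
        truth[[gid_a]] <- "convergent_partner_soma"
        truth[[gid_b]] <- "convergent_partner_gonidia"
        at <- b[3L, 2L] + spacing
      } else {
        gi <- gi + 1L; ni <- ni + 1L
        gid <- sprintf("gene%04d", gi)
        k <- null_k[ni]
        if (k == 1L) {
          ex <- cbind(start = at + (0:2) * (exon_w + intron_w))
          ex <- cbind(ex, end = ex[, 1L] + exon_w)
          colnames(ex) <- c("start", "end")
          models[[gid]] <- gene_model(gid, list(
            transcript_model(paste0(gid, ".1"), gid, chrom, "+", ex)))
          truth[[gid]] <- "null_single_isoform"
          at <- ex[nrow(ex), 2L] + spacing
        } else {
          # k isoforms from a (k+2)-exon base; isoform j > 1 skips
          # internal exon j, so all isoforms differ
          n_ex <- k + 2L
          base <- cbind(start = at + (0:(n_ex - 1L)) * (exon_w + intron_w))
          base <- cbind(base, end = base[, 1L] + exon_w)
          colnames(base) <- c("start", "end")
          txs <- lapply(seq_len(k), function(j) {
            ex <- if (j == 1L) base else base[-j, , drop = FALSE]
            transcript_model(sprintf("%s.%d", gid, j), gid, chrom, "+", ex)
          })
          models[[gid]] <- gene_model(gid, txs)
          truth[[gid]] <- "null_multi_isoform"
          at <- base[n_ex, 2L] + spacing
        }
      }
    }
    truth_df <- data.frame(gene_id = names(truth),
                           label = unlist(truth, use.names = FALSE),
                           stringsAsFactors = FALSE)
    truth_df <- truth_df[order(truth_df$gene_id), , drop = FALSE]
    rownames(truth_df) <- NULL
    list(models = models[order(names(models))], truth = truth_df,
         chrom_length = unname(at + spacing))
  })
}

#' Generate a synthetic expression table with planted effects
#'
#' Each transcript draws a log-normal baseline mean; cell-type means are
#' the baseline scaled by `2^(+-effect_log2)` according to the planted
#' label (CTSAI genes: isoform 1 soma-biased, isoform 2 gonidia-biased;
#' convergent partners: whole-transcript bias, opposite within the pair;
#' null genes: no bias). Replicate values are the cell-type mean times
#' multiplicative log-normal noise with the given coefficient of
#' variation (unit mean), so `replicate_cv = 0` yields exactly identical
#' replicates.
#'
#' @param models Named list of [gene_model()] from [generate_annotation()].
#' @param truth Truth data frame from [generate_annotation()].
#' @param params The same [simulation_params()].
#' @return An [expression_table()] with samples `soma_1..n, gonidia_1..n`.
#' @export
generate_expression <- function(models, truth, params) {
  stopifnot(inherits(params, "SimulationParams"))
  if (!setequal(truth$gene_id, names(models)))
    stop("truth table and models disagree on gene ids")
  with_local_seed(params$seed + 1L, {
    n_rep <- params$replicates_per_cell_type
    design <- sample_design(
      sample_id = c(paste0("soma_", seq_len(n_rep)),
                    paste0("gonidia_", seq_len(n_rep))),
      cell_type = rep(c("soma", "gonidia"), each = n_rep),
      replicate = rep(seq_len(n_rep), 2L))
    label <- stats::setNames(truth$label, truth$gene_id)
    idx <- transcript_index(models)
    e <- params$effect_log2
    # per-transcript bias exponent b: soma mean mu*2^b, gonidia mu*2^-b
    bias <- numeric(nrow(idx))
    for (i in seq_len(nrow(idx))) {
      lab <- label[[idx$gene_id[i]]]
      iso_no <- match(idx$transcript_id[i],
                      vapply(models[[idx$gene_id[i]]]$transcripts, `[[`,
                             character(1), "transcript_id"))
      bias[i] <- switch(lab,
        ctsai = if (iso_no == 1L) e else -e,
        convergent_partner_soma = e,
        convergent_partner_gonidia = -e,
        0)
    }
    mu <- stats::rlnorm(nrow(idx), params$baseline_fpkm_log_mean,
                        params$baseline_fpkm_log_sd)
    mean_soma <- mu * 2^bias
    mean_gonidia <- mu * 2^-bias
    sdlog <- sqrt(log(1 + params$replicate_cv^2))
    noise <- function(n) stats::rlnorm(n, meanlog = -sdlog^2 / 2,
                                       sdlog = sdlog)
    m <- matrix(0, nrow = nrow(idx), ncol = 2L * n_rep,
                dimnames = list(idx$transcript_id, design$sample_id))
    for (i in seq_len(nrow(idx))) {
      m[i, seq_len(n_rep)] <- mean_soma[i] * noise(n_rep)
      m[i, n_rep + seq_len(n_rep)] <- mean_gonidia[i] * noise(n_rep)
    }
    expression_table(m, stats::setNames(idx$gene_id, idx$transcript_id),
                     design)
  })
}

#' Generate matching per-base coverage tracks
#'
#' Deterministic given its inputs: per cell type, the depth over each base
#' is the sum over transcripts covering that base of
#' `round(mean FPKM in that cell type * depth_per_fpkm)`. Strand-agnostic,
#' mirroring unstranded library coverage.
#'
#' @param models Named list of [gene_model()].
#' @param expr An [expression_table()] whose transcripts all appear in
#'   `models`.
#' @param depth_per_fpkm Depth units contributed per FPKM (positive).
#' @param chrom_length Optional chromosome length(s); defaults to the
#'   rightmost exon end plus a margin.
#' @return A [coverage_track()].
#' @export
generate_coverage <- function(models, expr, depth_per_fpkm = 2,
                              chrom_length = NULL) {
  stopifnot(inherits(expr, "ExpressionTable"), depth_per_fpkm > 0)
  idx <- transcript_index(models)
  missing_tx <- setdiff(rownames(expr$fpkm), idx$transcript_id)
  if (length(missing_tx))
    stop("transcripts in expression without models: ",
         paste(utils::head(missing_tx, 5), collapse = ", "))
  tx_lookup <- stats::setNames(
    unlist(lapply(models, function(gm) gm$transcripts), recursive = FALSE,
           use.names = FALSE),
    idx$transcript_id)
  chroms <- unique(idx$chrom)
  if (is.null(chrom_length)) {
    chrom_length <- vapply(chroms, function(ch) {
      mx <- max(vapply(tx_lookup[idx$transcript_id[idx$chrom == ch]],
                       function(tx) max(tx$exons[, 2L]), numeric(1)))
      mx + 500
    }, numeric(1))
  } else if (is.null(names(chrom_length)) ||
             !all(chroms %in% names(chrom_length))) {
    if (length(chrom_length) != length(chroms))
      stop("chrom_length must be named or match the chromosome count")
    names(chrom_length) <- chroms
  }
  tracks <- lapply(c(soma = "soma", gonidia = "gonidia"), function(ct) {
    cols <- samples_of(expr$design, ct)
    mean_fpkm <- rowMeans(expr$fpkm[, cols, drop = FALSE])
    grs <- lapply(rownames(expr$fpkm), function(tid) {
      tx <- tx_lookup[[tid]]
      w <- round(mean_fpkm[[tid]] * depth_per_fpkm)
      gr <- GenomicRanges::GRanges(tx$chrom, exons_to_iranges(tx$exons))
      gr$w <- w
      gr
    })
    all_gr <- do.call(c, grs)
    GenomeInfoDb::seqlengths(all_gr) <-
      chrom_length[GenomeInfoDb::seqlevels(all_gr)]
    GenomicRanges::coverage(all_gr, weight = all_gr$w)
  })
  coverage_track(tracks)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_annotation()],
#' [generate_expression()] and [generate_coverage()] with one parameter
#' set.
#'
#' @param params A [simulation_params()].
#' @param depth_per_fpkm Passed to [generate_coverage()].
#' @return List with `models`, `truth`, `expression`, `coverage`,
#'   `chrom_length` and `params`.
#' @export
simulate_dataset <- function(params = simulation_params(),
                             depth_per_fpkm = 2) {
  ann <- generate_annotation(params)
  expr <- generate_expression(ann$models, ann$truth, params)
  cov <- generate_coverage(ann$models, expr, depth_per_fpkm,
                           chrom_length = ann$chrom_length)
  list(models = ann$models, truth = ann$truth, expression = expr,
       coverage = cov, chrom_length = ann$chrom_length, params = params)
}
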