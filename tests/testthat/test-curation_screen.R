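test_that("differential regions are exact interval set algebra", {
  tx <- function(id, ex) transcript_model(id, "g", "chrT", "+", ex)

  r <- differential_regions(tx("a", ivl(0, 100)),
                            tx("b", ivl(0, 100, 200, 300)))
  expect_equal(nrow(r$unique_to_iso1), 0L)
  expect_equal(unname(r$unique_to_iso2), unname(ivl(200, 300)))
  expect_equal(unname(r$shared), unname(ivl(0, 100)))

  r2 <- differential_regions(tx("a", ivl(0, 50)), tx("b", ivl(0, 50)))
  expect_equal(nrow(r2$unique_to_iso1), 0L)
  expect_equal(nrow(r2$unique_to_iso2), 0L)

  r3 <- differential_regions(tx("a", ivl(0, 50)), tx("b", ivl(25, 75)))
  expect_equal(unname(r3$unique_to_iso1), unname(ivl(0, 25)))
  expect_equal(unname(r3$unique_to_iso2), unname(ivl(50, 75)))
  expect_equal(unname(r3$shared), unname(ivl(25, 50)))

  expect_error(differential_regions(
    tx("a", ivl(0, 50)),
    transcript_model("b", "g", "chrU", "+", ivl(0, 50))),
    "different chromosomes")
})

test_that("differential regions match per-base brute force on random pairs", {
  set.seed(303)
  for (i in 1:100) {
    ex1 <- random_exons(); ex2 <- random_exons()
    tx1 <- transcript_model("a", "g", "chrT", "+", ex1)
    tx2 <- transcript_model("b", "g", "chrT", "+", ex2)
    r <- differential_regions(tx1, tx2)
    brute <- oracle_differential_bases(ex1, ex2)
    expect_equal(intervals_to_bases(r$unique_to_iso1), brute$unique1)
    expect_equal(intervals_to_bases(r$unique_to_iso2), brute$unique2)
    expect_equal(intervals_to_bases(r$shared), brute$shared)
    # the three sets partition the exonic union
    expect_equal(sort(c(intervals_to_bases(r$unique_to_iso1),
                        intervals_to_bases(r$unique_to_iso2),
                        intervals_to_bases(r$shared))),
                 sort(union(intervals_to_bases(ex1),
                            intervals_to_bases(ex2))))
  }
})

test_that("read-density check enforces inclusive depth and coverage cutoffs", {
  tx1 <- transcript_model("a", "g", "chrT", "+", ivl(0, 100, 100, 200))
  tx2 <- transcript_model("b", "g", "chrT", "+", ivl(100, 300))
  regions <- differential_regions(tx1, tx2)  # u1 [0,100), u2 [200,300)

  cov <- make_coverage(20, 300, 20, 300)
  expect_true(read_density_check(cov, regions)$rd_pass)

  # unique region of the gonidial isoform empty of reads -> fail
  cov2 <- make_coverage(20, 300, c(20, 0), c(200, 100))
  chk <- read_density_check(cov2, regions)
  expect_true(chk$iso1_pass)
  expect_false(chk$iso2_pass)
  expect_false(chk$rd_pass)

  # boundary: depth exactly 5.0 with full coverage passes (inclusive)
  cov3 <- make_coverage(5, 300, 5, 300)
  expect_true(read_density_check(cov3, regions)$rd_pass)
  cov4 <- make_coverage(4.99, 300, 5, 300)
  expect_false(read_density_check(cov4, regions)$rd_pass)

  # region beyond the coverage array is a consistency error
  short <- make_coverage(20, 150, 20, 150)
  expect_error(read_density_check(short, regions), "beyond coverage")
})

test_that("relative-support score evaluates the normalized switch formula", {
  tx1 <- transcript_model("a", "g", "chrT", "+", ivl(0, 200))
  tx2 <- transcript_model("b", "g", "chrT", "+", ivl(100, 300))
  regions <- differential_regions(tx1, tx2)
  # u1 [0,100): soma 40 / gonidia 4; u2 [200,300): soma 4 / gonidia 40;
  # shared [100,200): 40 in both
  cov <- make_coverage(c(40, 40, 4), c(100, 100, 100),
                       c(4, 40, 40), c(100, 100, 100))
  rel <- relative_support_score(cov, regions, pseudodepth = 0)
  expect_equal(rel$rel_score, log2(10) - log2(1 / 10), tolerance = 1e-12)
  expect_true(rel$rel_pass)

  # all means equal across cell types -> score 0
  flat <- make_coverage(10, 300, 10, 300)
  rel0 <- relative_support_score(flat, regions, pseudodepth = 0)
  expect_equal(rel0$rel_score, 0)
  expect_false(rel0$rel_pass)

  # a pure overall expression difference (soma 10x everywhere) cancels
  biased <- make_coverage(100, 300, 10, 300)
  relb <- relative_support_score(biased, regions, pseudodepth = 0)
  expect_equal(relb$rel_score, 0)
  expect_false(relb$rel_pass)

  # empty shared region: undefined, fails with reason
  tx3 <- transcript_model("c", "g", "chrT", "+", ivl(250, 300))
  disjoint <- differential_regions(tx1, tx3)
  reld <- relative_support_score(cov, disjoint)
  expect_false(reld$rel_pass)
  expect_identical(reld$reason, "empty shared region")
})

test_that("scaling one cell type's whole coverage leaves the score unchanged", {
  tx1 <- transcript_model("a", "g", "chrT", "+", ivl(0, 200))
  tx2 <- transcript_model("b", "g", "chrT", "+", ivl(100, 300))
  regions <- differential_regions(tx1, tx2)
  cov <- make_coverage(c(30, 50, 8), c(100, 100, 100),
                       c(6, 45, 33), c(100, 100, 100))
  base <- relative_support_score(cov, regions, pseudodepth = 0)
  for (k in c(0.5, 3, 10)) {
    scaled <- make_coverage(k * c(30, 50, 8), c(100, 100, 100),
                            c(6, 45, 33), c(100, 100, 100))
    s <- relative_support_score(scaled, regions, pseudodepth = 0)
    expect_equal(s$rel_score, base$rel_score, tolerance = 1e-9)
  }
})

test_that("convergent pair detection respects strand and 3' geometry", {
  plus <- function(id, ex) make_gene(id, list(ex), strand = "+")
  minus <- function(id, ex) make_gene(id, list(ex), strand = "-")

  # convergent: + gene then - gene, 3'-most exons overlap 50 bp
  conv <- list(A = plus("A", ivl(0, 200, 300, 500)),
               B = minus("B", ivl(450, 650, 750, 950)))
  found <- detect_convergent_pairs(conv)
  expect_equal(nrow(found), 1L)
  expect_equal(found$overlap_bp, 50L)

  # same strand: not convergent
  same <- list(A = plus("A", ivl(0, 200, 300, 500)),
               B = plus("B", ivl(450, 650, 750, 950)))
  expect_equal(nrow(detect_convergent_pairs(same)), 0L)

  # divergent (5' ends overlap): not convergent
  div <- list(A = minus("A", ivl(0, 200, 300, 500)),
              B = plus("B", ivl(450, 650, 750, 950)))
  expect_equal(nrow(detect_convergent_pairs(div)), 0L)

  # opposite-bias annotation from gene-level ERs
  er <- c(A = 4, B = 0.2)
  f2 <- detect_convergent_pairs(conv, gene_er = er)
  expect_true(f2$opposite_bias)
  f3 <- detect_convergent_pairs(conv, gene_er = c(A = 4, B = 3))
  expect_false(f3$opposite_bias)
})

test_that("convergent detection is symmetric and translation invariant", {
  d <- generate_annotation(simulation_params(n_genes = 30L, n_ctsai = 3L,
                                             n_convergent_pairs = 3L,
                                             seed = 31L))
  base <- detect_convergent_pairs(d$models)
  rev_order <- detect_convergent_pairs(rev(d$models))
  expect_equal(base, rev_order, ignore_attr = TRUE)
  shifted <- lapply(d$models, function(gm) {
    gm$transcripts <- lapply(gm$transcripts, function(tx) {
      tx$exons <- tx$exons + 10000
      tx
    })
    gm
  })
  sh <- detect_convergent_pairs(shifted)
  expect_equal(sh[, c("gene_a", "gene_b", "overlap_bp")],
               base[, c("gene_a", "gene_b", "overlap_bp")],
               ignore_attr = TRUE)
})

test_that("curation partitions candidates and flags miscalled convergent pairs", {
  d <- simulate_dataset(simulation_params(n_genes = 80L, n_ctsai = 10L,
                                          n_convergent_pairs = 3L,
                                          seed = 17L))
  res <- detect_ctsai(d$expression, d$models)
  is_cand <- vapply(res$detection$records, `[[`, character(1),
                    "verdict") == "candidate"
  records <- res$detection$records[is_cand]
  models <- d$models

  # misdeclare each planted convergent pair as one two-isoform gene and
  # append it to the candidate list
  pairs <- detect_convergent_pairs(d$models)
  th <- ctsai_thresholds()
  for (k in seq_len(nrow(pairs))) {
    ga <- d$models[[pairs$gene_a[k]]]$transcripts[[1]]
    gb <- d$models[[pairs$gene_b[k]]]$transcripts[[1]]
    pg <- paste0("fused", k)
    tx1 <- transcript_model(paste0(pg, ".1"), pg, ga$chrom, ga$strand,
                            ga$exons)
    tx2 <- transcript_model(paste0(pg, ".2"), pg, gb$chrom, gb$strand,
                            gb$exons)
    models[[pg]] <- gene_model(pg, list(tx1, tx2))
    s1 <- isoform_cell_type_stats(d$expression, ga$transcript_id, th)
    s2 <- isoform_cell_type_stats(d$expression, gb$transcript_id, th)
    s1$transcript_id <- tx1$transcript_id
    s2$transcript_id <- tx2$transcript_id
    records[[length(records) + 1L]] <-
      apply_filter_cascade(pg, list(s1, s2), th)
  }

  cur <- curate(records, models, d$coverage)
  expect_equal(nrow(cur$results), length(records))
  # partition: exactly one final status each, counts add up
  expect_true(all(cur$results$final %in%
                    c("retained", "excluded_RD", "excluded_REL",
                      "excluded_CT")))
  expect_equal(cur$summary$retained + cur$summary$excluded_RD +
                 cur$summary$excluded_REL + cur$summary$excluded_CT,
               cur$summary$n_input)
  fused <- grepl("^fused", cur$results$gene_id)
  expect_true(all(cur$results$final[fused] == "excluded_CT"))
  planted <- d$truth$gene_id[d$truth$label == "ctsai"]
  true_rows <- cur$results$gene_id %in% planted
  expect_true(all(cur$results$final[true_rows] == "retained"))

  empty <- curate(list(), models, d$coverage)
  expect_equal(nrow(empty$results), 0L)
  expect_equal(empty$summary$n_input, 0L)
})
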