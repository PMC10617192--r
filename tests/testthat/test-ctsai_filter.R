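make_stats <- function(ER, p, id = "t") {
  structure(list(transcript_id = id, mean_soma = NA_real_,
                 mean_gonidia = NA_real_, ER = ER, log2ER = log2(ER),
                 p_value = p),
            class = "IsoformStats")
}

test_that("per-isoform statistics follow the ratio definition", {
  tab <- make_table(list(t1 = c(2, 2, 2, 2),
                         t2 = c(8, 8, 2, 2),
                         t3 = c(4, 4, 0, 0)),
                    c(t1 = "g1", t2 = "g2", t3 = "g3"))
  s1 <- isoform_cell_type_stats(tab, "t1")
  expect_equal(s1$ER, 1)
  expect_equal(s1$log2ER, 0)

  s2 <- isoform_cell_type_stats(tab, "t2", ctsai_thresholds(pseudocount = 0))
  expect_equal(s2$ER, 4)
  expect_equal(s2$log2ER, 2)

  # zero gonidial expression survives via the pseudocount: 4.01 / 0.01
  s3 <- isoform_cell_type_stats(tab, "t3")
  expect_equal(s3$ER, 401)
  expect_true(is.finite(s3$log2ER))

  expect_error(isoform_cell_type_stats(tab, "absent"), "not in expression")
})

test_that("differential test has the degenerate noise-free contract", {
  expect_equal(two_group_isoform_test(c(5, 5), c(5, 5)), 1)
  expect_equal(two_group_isoform_test(c(8, 8), c(2, 2)), 0)
  expect_error(two_group_isoform_test(c(5), c(5, 5)), ">= 2 replicates")
  expect_error(two_group_isoform_test(c(5, -1), c(5, 5)), "non-negative")
})

test_that("differential test matches the textbook pooled-t computation", {
  expect_equal(two_group_isoform_test(c(6, 10), c(2, 3)),
               oracle_pooled_t(c(6, 10), c(2, 3)), tolerance = 1e-10)
  set.seed(202)
  for (i in 1:100) {
    n1 <- sample(2:6, 1L); n2 <- sample(2:6, 1L)
    soma <- stats::rlnorm(n1, 2, 1)
    gonidia <- stats::rlnorm(n2, 2, 1)
    expect_equal(two_group_isoform_test(soma, gonidia),
                 oracle_pooled_t(soma, gonidia), tolerance = 1e-10)
  }
})

test_that("filter cascade applies the three stages with strict thresholds", {
  th <- ctsai_thresholds()

  r <- apply_filter_cascade("g", list(make_stats(4, 0.05, "a"),
                                      make_stats(0.25, 0.04, "b")), th)
  expect_true(r$passed_stage1 && r$passed_stage2 && r$passed_stage3)
  expect_equal(r$B, 16)
  expect_equal(r$aggregate_p, 0.002)
  expect_identical(r$verdict, "candidate")
  expect_identical(r$iso1$transcript_id, "a")  # higher-ER isoform first

  # 0.6 >= 1/2: opposite-bias criterion fails
  r2 <- apply_filter_cascade("g", list(make_stats(4, 0.01, "a"),
                                       make_stats(0.6, 0.01, "b")), th)
  expect_false(r2$passed_stage1)
  expect_identical(r2$verdict, "rejected")

  # B = 3 / 0.45 = 6.67 < 8: combined-bias criterion fails
  r3 <- apply_filter_cascade("g", list(make_stats(3, 0.01, "a"),
                                       make_stats(0.45, 0.01, "b")), th)
  expect_true(r3$passed_stage1)
  expect_false(r3$passed_stage2)
  expect_equal(r3$B, 3 / 0.45)

  # exact threshold ties fail (strict inequalities)
  r4 <- apply_filter_cascade("g", list(make_stats(4, 0.1, "a"),
                                       make_stats(0.25, 0.01, "b")), th)
  expect_false(r4$passed_stage3)

  expect_error(apply_filter_cascade("g", list(make_stats(1, 1))),
               "exactly two isoforms")
})

test_that("stage nesting and the aggregate-p identity hold on random genes", {
  set.seed(77)
  for (i in 1:200) {
    s <- list(make_stats(stats::rlnorm(1, 0, 2), stats::runif(1), "a"),
              make_stats(stats::rlnorm(1, 0, 2), stats::runif(1), "b"))
    r <- apply_filter_cascade("g", s)
    expect_true(!r$passed_stage2 || r$passed_stage1)
    expect_true(!r$passed_stage3 || r$passed_stage2)
    expect_identical(r$aggregate_p, r$iso1$p_value * r$iso2$p_value)
    expect_gte(r$B, 1)
  }
})

test_that("stage 1 equals the |log2 ER| > 1 opposite-signs phrasing", {
  set.seed(78)
  th <- ctsai_thresholds()
  for (i in 1:200) {
    e1 <- stats::rlnorm(1, 0, 2); e2 <- stats::rlnorm(1, 0, 2)
    r <- apply_filter_cascade("g", list(make_stats(e1, 0.5, "a"),
                                        make_stats(e2, 0.5, "b")), th)
    alt <- abs(log2(e1)) > 1 && abs(log2(e2)) > 1 &&
      sign(log2(e1)) * sign(log2(e2)) < 0
    expect_identical(r$passed_stage1, alt)
  }
})

test_that("tightening thresholds never adds candidates", {
  d <- simulate_dataset(simulation_params(n_genes = 80L, n_ctsai = 10L,
                                          n_convergent_pairs = 2L,
                                          seed = 15L))
  base <- detect_ctsai(d$expression, d$models)
  for (th in list(ctsai_thresholds(tau_B = 32),
                  ctsai_thresholds(tau_p = 0.01),
                  ctsai_thresholds(tau_bias = 4))) {
    tight <- detect_ctsai(d$expression, d$models, thresholds = th)
    expect_true(all(tight$candidates %in% base$candidates))
  }
  none <- detect_ctsai(d$expression, d$models,
                       thresholds = ctsai_thresholds(tau_B = Inf))
  expect_length(none$candidates, 0L)
})

test_that("relabeling the cell types inverts ERs and keeps verdicts", {
  d <- simulate_dataset(simulation_params(n_genes = 40L, n_ctsai = 5L,
                                          n_convergent_pairs = 1L,
                                          seed = 21L))
  tab <- d$expression
  swapped_design <- sample_design(
    tab$design$sample_id,
    ifelse(tab$design$cell_type == "soma", "gonidia", "soma"),
    tab$design$replicate)
  tab_sw <- expression_table(tab$fpkm, tab$tx2gene, swapped_design)
  th <- ctsai_thresholds(pseudocount = 0)
  res <- detect_ctsai(tab, d$models, thresholds = th)
  res_sw <- detect_ctsai(tab_sw, d$models, thresholds = th)
  expect_setequal(res_sw$candidates, res$candidates)
  for (k in seq_along(res$detection$records)) {
    r <- res$detection$records[[k]]
    r_sw <- res_sw$detection$records[[k]]
    # iso1/iso2 swap roles; B and the aggregate are invariant
    expect_equal(r_sw$B, r$B, tolerance = 1e-12)
    expect_equal(r_sw$aggregate_p, r$aggregate_p, tolerance = 1e-12)
    expect_equal(r_sw$iso1$ER, 1 / r$iso2$ER, tolerance = 1e-12)
    expect_identical(r_sw$verdict, r$verdict)
  }
})

test_that("noise-free planted genes are recovered exactly", {
  p <- simulation_params(n_genes = 50L, n_ctsai = 5L,
                         n_convergent_pairs = 0L, effect_log2 = 2,
                         replicate_cv = 0, seed = 13L)
  d <- simulate_dataset(p)
  res <- detect_ctsai(d$expression, d$models)
  planted <- d$truth$gene_id[d$truth$label == "ctsai"]
  expect_setequal(res$candidates, planted)
  f <- res$detection$funnel
  expect_true(f$n_input >= f$stage1 && f$stage1 >= f$stage2 &&
                f$stage2 >= f$stage3)
})
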