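# Catalogue summary statistics and fixture arithmetic.

test_that("density and incidence reproduce the survey arithmetic", {
  tot <- load_fixture("totals")
  expect_equal(density_kb_per_ssr(tot[["total_length_bp"]],
                                  tot[["n_ssrs_ge15"]]), 6.55)
  expect_equal(density_kb_per_ssr(tot[["total_length_bp"]],
                                  tot[["n_ssrs_ge18"]]), 10.81)
  expect_equal(incidence_pct(tot[["n_ssrs_ge15"]],
                             tot[["n_transcripts"]]), 17.21)
  expect_equal(incidence_pct(tot[["n_ssrs_ge18"]],
                             tot[["n_transcripts"]]), 10.43)
  expect_equal(density_kb_per_ssr(1000, 1), 1.00)
  expect_equal(incidence_pct(0, 100), 0.00)
  expect_warning(expect_true(is.na(density_kb_per_ssr(1000, 0))),
                 "undefined")
  expect_error(incidence_pct(1, 0), "positive")
})

test_that("length-threshold filtering reconstructs the 18 bp column", {
  t4 <- load_fixture("table4")
  t2 <- load_fixture("table2")
  perf18 <- t2$n_ge18[t2$classification == "perfect"]
  got <- vapply(1:6, function(k) {
    apply_length_threshold(stats::setNames(t4[[k + 1L]], t4$copies), k, 18)
  }, numeric(1))
  expect_equal(got, c(21, 1764, 770, 78, 109, 932))
  expect_equal(got, as.numeric(perf18))
  # monotone in the threshold, per unit size
  for (k in 1:6) {
    h <- stats::setNames(t4[[k + 1L]], t4$copies)
    expect_gte(apply_length_threshold(h, k, 15),
               apply_length_threshold(h, k, 18))
  }
  # hexa catalogues are identical at both thresholds (3 x 6 = 18)
  h6 <- stats::setNames(t4$hexa, t4$copies)
  expect_equal(apply_length_threshold(h6, 6, 15),
               apply_length_threshold(h6, 6, 18))
  expect_equal(apply_length_threshold(stats::setNames(integer(0),
                                                      character(0)), 2, 18),
               0L)
})

test_that("copy-number modes rank the survey histogram as printed", {
  modes <- copy_number_modes(load_fixture("table4"))
  expect_equal(modes$copies[1:4], c(3, 5, 8, 9))
  expect_equal(modes$share_pct[1:4], c(19.81, 18.13, 14.09, 9.16))
  expect_equal(copy_number_modes(c("7" = 12))$share_pct, 100)
  # uniform histogram: four ties at 25%, ranked by ascending copy number
  u <- copy_number_modes(c("9" = 5, "3" = 5, "6" = 5, "4" = 5))
  expect_equal(u$copies, c(3, 4, 6, 9))
  expect_equal(u$share_pct, rep(25, 4))
  expect_error(copy_number_modes(numeric(0)), "empty")
})

test_that("summaries have consistent marginals on planted catalogues", {
  ts <- transcript_set(
    c("t1", "t2"),
    c(paste0("CTGTCGTCAGTCGTACGTGT", strrep("AG", 10),
             "CTGTCGTACGATCGTACGAT", strrep("CT", 9), "GCATGCTAGTC"),
      paste0("CTGTCGTCAGTCGTACGTGT", strrep("GAA", 7),
             "CTGTCGTACGATCGTACGAT")))
  loci <- classify_catalogue(ts, mining_config(18))
  sm <- summarize_catalogue(loci, ts, threshold_bp = 18)
  expect_equal(sm$n_ssrs, 3L)
  expect_equal(unname(sm$by_unit_size$perfect[2:3]), c(2L, 1L))
  expect_equal(sum(sm$by_classification), sm$n_ssrs)
  expect_equal(round_half_up(100 * sm$by_unit_size$perfect[["di"]] /
                               sm$by_classification[["perfect"]]), 66.67)
  expect_equal(names(sm$by_motif_class)[1], "AG")

  # empty catalogue -> all-zero summary
  sm0 <- summarize_catalogue(classify_catalogue("ACGTTGCA"),
                             threshold_bp = 18)
  expect_equal(sm0$n_ssrs, 0L)
  expect_true(all(sm0$by_classification == 0L))
})

test_that("summary marginals are consistent on simulated catalogues", {
  sim <- generate_transcripts(simulation_spec(n_transcripts = 150,
                                              ssr_plant_rate = 1.2,
                                              seed = 52))
  loci <- classify_catalogue(sim$transcripts, mining_config(18))
  sm <- summarize_catalogue(loci, sim$transcripts, 18)
  expect_equal(sum(sm$by_classification), sm$n_ssrs)
  expect_equal(sum(sm$by_unit_size$perfect),
               sm$by_classification[["perfect"]])
  expect_equal(sum(sm$by_unit_size$imperfect),
               sm$by_classification[["imperfect"]])
  expect_equal(sum(unlist(sm$by_compound_subtype["compound_perfect"])),
               sm$by_classification[["compound_perfect"]])
  expect_equal(sum(sm$by_motif_class), sm$by_classification[["perfect"]])
  expect_equal(sum(unlist(sm$copy_number_histogram)),
               sm$by_classification[["perfect"]])
  # classification frequencies sum to 100 within rounding
  freq <- round_half_up(100 * sm$by_classification / sm$n_ssrs)
  expect_lt(abs(sum(freq) - 100), 0.05)
})

test_that("fixture loader exposes the printed totals and rejects unknown names", {
  t4 <- load_fixture("table4")
  expect_equal(sum(t4[, -1]), 6485)
  t2 <- load_fixture("table2")
  expect_equal(sum(t2$n_ge18[t2$classification == "perfect"]), 3674)
  expect_equal(sum(t2$n_ge15), 7324)
  expect_equal(sum(t2$n_ge18), 4440)
  expect_error(load_fixture("table9"), "unknown")
})
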