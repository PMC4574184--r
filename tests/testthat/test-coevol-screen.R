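test_that("convergence filter is strict at its thresholds", {
  rec <- tibble::tibble(
    gene = c("a", "b", "c"),
    correlation = c(-0.2, 0.3, -0.5),
    pp = c(0.1, 0.9, 0.5),
    min_ess = c(301, 300, 500),
    root_ess = c(51, 500, 50)
  )
  kept <- convergence_filter(rec)
  expect_equal(kept$gene, "a") # 300 and 50 are not strictly greater
  expect_equal(attr(kept, "convergence"), list(kept = 1L, dropped = 2L))
  expect_error(convergence_filter(rec[, 1:3]), "min_ess")

  n <- 100
  rec2 <- tibble::tibble(gene = paste0("g", 1:n), correlation = 0.1,
                         pp = 0.5,
                         min_ess = c(rep(100, 20), rep(1000, 80)),
                         root_ess = 100)
  expect_equal(nrow(convergence_filter(rec2)), 80)
})

test_that("cutoff calibration is conservative and handles degeneracies", {
  # evenly spaced grid: largest cutoff keeping <= 5% in the two tails
  pps <- seq_len(2000) / 2001
  cal <- calibrate_pp_cutoffs(pps, 0.05)
  expect_equal(cal$cutoff, 50 / 2001, tolerance = 1e-9)
  expect_lte(cal$realized_fraction, 0.05)
  expect_equal(cal$n_significant, 100L)

  # all-central pps: no tail below 0.5 exists; cutoff just under 0.5
  cal2 <- calibrate_pp_cutoffs(rep(0.5, 10))
  expect_equal(cal2$realized_fraction, 0)
  expect_lt(cal2$cutoff, 0.5)
  expect_gt(cal2$cutoff, 0.49)

  # symmetric pair forces both tails at once: 2/20 > 5% is unachievable
  expect_warning(
    cal3 <- calibrate_pp_cutoffs(c(0.001, 0.999, rep(0.5, 18)), 0.05),
    "unachievable"
  )
  expect_equal(cal3$cutoff, 0)
  expect_equal(cal3$realized_fraction, 0)

  # shrinking the target never grows the cutoff
  set.seed(61)
  pps4 <- runif(500)
  cuts <- vapply(c(0.2, 0.1, 0.05, 0.01),
                 function(t) calibrate_pp_cutoffs(pps4, t)$cutoff,
                 numeric(1))
  expect_true(all(diff(cuts) <= 0))
  for (t in c(0.2, 0.1, 0.05, 0.01)) {
    expect_lte(calibrate_pp_cutoffs(pps4, t)$realized_fraction, t)
  }
})

test_that("classification partitions genes by cutoff and sign", {
  rec <- tibble::tibble(
    pp = c(0.01, 0.984, 0.5, 0.3, 0.7, 0.017),
    correlation = c(-0.4, 0.5, 0.1, -0.2, 0.3, -0.1)
  )
  cls <- classify_and_count(rec, 0.017)
  expect_equal(cls$neg_sig, 2L)   # 0.01 and the boundary 0.017
  expect_equal(cls$pos_sig, 1L)   # 0.984 >= 0.983
  expect_equal(cls$neg_nonsig, 1L)
  expect_equal(cls$pos_nonsig, 2L)
  total <- cls$neg_sig + cls$pos_sig + cls$neg_nonsig + cls$pos_nonsig
  expect_equal(total, nrow(rec))
})

test_that("sign chi-square matches hand values in both modes", {
  counts <- list(neg_sig = 50, pos_sig = 10, neg_nonsig = 25, pos_nonsig = 15)
  gof <- sign_chisq(counts, "gof_pooled") # 75 vs 25 against 50:50
  expect_equal(gof$statistic, 25)
  expect_equal(gof$df, 1)

  even <- list(neg_sig = 25, pos_sig = 25, neg_nonsig = 25, pos_nonsig = 25)
  expect_equal(sign_chisq(even, "gof_pooled")$statistic, 0)
  expect_equal(sign_chisq(even, "gof_pooled")$p.value, 1)

  # proportional rows are independent
  prop <- list(neg_sig = 30, pos_sig = 10, neg_nonsig = 60, pos_nonsig = 20)
  expect_equal(sign_chisq(prop, "independence")$statistic, 0,
               tolerance = 1e-12)
})

test_that("Fisher enrichment matches complete enumeration", {
  expect_equal(enrichment_fisher(5, 5, 5, 5), 1)
  expect_lt(enrichment_fisher(10, 0, 0, 10), 1e-4)
  expect_equal(enrichment_fisher(10, 0, 0, 10),
               fisher_oracle(10, 0, 0, 10), tolerance = 1e-9)
  # transposing the table preserves p
  expect_equal(enrichment_fisher(3, 7, 9, 2), enrichment_fisher(3, 9, 7, 2),
               tolerance = 1e-12)
  expect_error(enrichment_fisher(-1, 1, 1, 1), "negative")

  set.seed(62)
  for (i in 1:25) {
    cells <- as.integer(rmultinom(1, sample(5:40, 1), rep(0.25, 4)))
    expect_equal(
      enrichment_fisher(cells[1], cells[2], cells[3], cells[4]),
      fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
      tolerance = 1e-9
    )
  }
})

test_that("full screen recovers a planted negative:positive ratio", {
  tab <- simulate_coevol_table(3748, fractions = c(0.95, 0.04, 0.01),
                               beta = 50, ess_fail_rate = 0.05, seed = 63)
  sc <- coevol_screen(tab)
  expect_lte(sc$realized_fraction, 0.05)
  expect_equal(sc$n_converged + sc$n_dropped, 3748)
  frac_neg <- sc$counts$neg_sig / (sc$counts$neg_sig + sc$counts$pos_sig)
  expect_gt(frac_neg, 0.7)
  expect_lt(frac_neg, 0.9)
  expect_equal(sum(unlist(sc$counts)), sc$n_converged)
  # both nominal and calibrated fractions are reported
  expect_true(is.finite(sc$nominal_fraction))
  expect_true(sc$chisq$p.value >= 0 && sc$chisq$p.value <= 1)
  # the significant pool alone is strongly negative-skewed
  sig_only <- list(neg_sig = sc$counts$neg_sig, pos_sig = sc$counts$pos_sig,
                   neg_nonsig = 0L, pos_nonsig = 0L)
  expect_lt(sign_chisq(sig_only, "gof_pooled")$p.value, 0.001)
})
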