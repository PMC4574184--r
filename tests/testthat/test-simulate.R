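test_that("Yule trees are ultrametric, binary, and seed-deterministic", {
  t2 <- simulate_yule_tree(2, 1, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  expect_true(is_ultrametric(t2, rel_tol = 1e-12))

  t30a <- simulate_yule_tree(30, 0.1, seed = 99)
  t30b <- simulate_yule_tree(30, 0.1, seed = 99)
  expect_identical(write_newick(t30a), write_newick(t30b))
  expect_true(ape::is.binary(t30a))
  expect_true(is_ultrametric(t30a, rel_tol = 1e-9))
  expect_error(simulate_yule_tree(1), "at least 2")
})

test_that("Yule tree height matches the pure-birth expectation", {
  # E[height] = sum_{k=2}^{n} 1/(k lambda): the root starts with 2
  # lineages and the tree is sampled one exponential wait after the
  # (n-1)th split
  n <- 20
  lambda <- 0.5
  hs <- vapply(1:300, function(i) {
    max(ape::node.depth.edgelength(simulate_yule_tree(n, lambda, seed = i)))
  }, numeric(1))
  expected <- sum(1 / (2:n)) / lambda
  se <- sd(hs) / sqrt(length(hs))
  expect_lt(abs(mean(hs) - expected), 4 * se)
})

test_that("BM increments standardise to unit variance on a cherry", {
  tr <- read_newick("(A:1,B:1);")
  contrasts <- vapply(1:4000, function(i) {
    tt <- simulate_bm_traits(tr, seed = i)
    pic_contrasts(tr, setNames(tt$trait1, tt$species))$contrast
  }, numeric(1))
  expect_equal(var(contrasts), 1, tolerance = 0.06)
})

test_that("degenerate BM covariance gives constant traits", {
  tr <- simulate_yule_tree(8, 0.5, seed = 3)
  tt <- simulate_bm_traits(tr, Sigma = matrix(0, 2, 2), seed = 4)
  expect_equal(tt$trait1, rep(0, 8))
  expect_equal(tt$trait2, rep(0, 8))
  expect_error(
    simulate_bm_traits(tr, Sigma = matrix(c(1, 2, 2, 1), 2)),
    "positive semidefinite"
  )
})

test_that("BM trait correlation is recovered through contrasts", {
  rs <- vapply(1:30, function(i) {
    tr <- simulate_yule_tree(100, 0.2, seed = 1000 + i)
    tt <- simulate_bm_traits(tr, rho = 0.7, seed = 2000 + i)
    correlate_traits(tt, tr, "trait1", "trait2")$estimate
  }, numeric(1))
  expect_equal(mean(rs), 0.7, tolerance = 0.05)
})

test_that("simulated maps truncate true lengths as order statistics predict", {
  # m = 2: observed span of two uniform points, expectation L/3
  spans <- vapply(1:2000, function(i) {
    simulate_genetic_map(90, 2, seed = i)$map$length_cM
  }, numeric(1))
  expect_equal(mean(spans), 30, tolerance = 1.5)
  expect_true(all(spans <= 90))

  # dense markers recover the truth
  dense <- simulate_genetic_map(90, 5000, seed = 1)$map$length_cM
  expect_equal(dense, 90, tolerance = 0.5)

  # reproducible
  a <- simulate_genetic_map(c(100, 80), 10, seed = 7)
  b <- simulate_genetic_map(c(100, 80), 10, seed = 7)
  expect_identical(a, b)
  expect_equal(a$true_total_cM, 180)
  expect_error(simulate_genetic_map(100, 1), "at least 2")
})

test_that("map correction reduces error relative to the observed length", {
  # the headline property: corrected lengths are closer to the truth
  err_obs <- err_cor <- numeric(0)
  for (m in c(5, 10, 25)) {
    for (i in 1:70) {
      sim <- simulate_genetic_map(c(120, 100, 80), m, seed = 3000 + 100 * m + i)
      corr <- correct_map_length(sim$map)
      err_obs <- c(err_obs, abs(corr$observed_length_cM - sim$true_total_cM))
      err_cor <- c(err_cor, abs(corr$corrected_length_cM - sim$true_total_cM))
    }
  }
  expect_lt(mean(err_cor), mean(err_obs))
})

test_that("codon simulator respects bias limits and validity", {
  aln <- simulate_codon_sequences(5, 100, bias = 0.4, seed = 8)
  expect_silent(validate_codon_alignment(aln))
  expect_equal(nchar(aln$seq), rep(300, 5))
  expect_identical(aln, simulate_codon_sequences(5, 100, bias = 0.4, seed = 8))
  expect_error(simulate_codon_sequences(1, 10, bias = 2), "bias")
})

test_that("coevol table generator produces a consistent mixture", {
  tab <- simulate_coevol_table(5000, fractions = c(0.9, 0.08, 0.02),
                               beta = 50, seed = 9)
  expect_equal(nrow(tab), 5000)
  expect_identical(tab, simulate_coevol_table(5000,
                                              fractions = c(0.9, 0.08, 0.02),
                                              beta = 50, seed = 9))
  # sign of coefficient consistent with pp side
  expect_true(all(tab$correlation[tab$pp > 0.5] > 0))
  expect_true(all(tab$correlation[tab$pp < 0.5] < 0))
  # signal genes concentrate in the tails
  expect_gt(mean(tab$pp[tab$truth == "positive"]), 0.9)
  expect_lt(mean(tab$pp[tab$truth == "negative"]), 0.1)
  expect_error(simulate_coevol_table(10, fractions = c(0.5, 0.1, 0.1)),
               "sum to 1")

  # null-only table: calibrated screen stays within its target
  null_tab <- simulate_coevol_table(2000, fractions = c(1, 0, 0), seed = 10)
  cal <- calibrate_pp_cutoffs(null_tab$pp, 0.05)
  expect_lte(cal$realized_fraction, 0.05)
})

test_that("a full synthetic study assembles every input", {
  st <- simulate_study(n_species = 8, n_genes = 200, seed = 5)
  expect_s3_class(st$tree, "phylo")
  expect_equal(nrow(st$traits), 8)
  expect_equal(dplyr::n_distinct(st$maps$species), 8)
  expect_equal(nrow(st$coevol), 200)
  expect_true(is_ultrametric(st$tree, rel_tol = 1e-9))
  expect_silent(validate_codon_alignment(st$alignments))
})
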