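test_that("contrasts follow Felsenstein's recursion on hand-checked trees", {
  tr2 <- read_newick("(A:1,B:1);")
  cs <- pic_contrasts(tr2, c(A = 3, B = 1))
  expect_equal(abs(cs$contrast), 2 / sqrt(2), tolerance = 1e-9)

  tr3 <- read_newick("((A:1,B:1):1,C:2);")
  cs3 <- pic_contrasts(tr3, c(A = 1, B = 3, C = 4))
  expect_equal(sort(abs(cs3$contrast)), sort(c(2 / sqrt(2), 2 / sqrt(3.5))),
               tolerance = 1e-6)
  # working value at the cherry is the weighted average, branch extended by
  # v1 v2/(v1+v2): contrast variance at the root is 1.5 + 2
  expect_equal(sort(cs3$sum_v), c(2, 3.5))
  nv <- attr(cs3, "node_values")
  expect_true(2 %in% round(nv, 9))

  # identical tip values => all contrasts zero
  yt <- simulate_yule_tree(12, 0.3, seed = 2)
  cs0 <- pic_contrasts(yt, setNames(rep(5, 12), yt$tip.label))
  expect_equal(cs0$contrast, rep(0, 11))
})

test_that("contrasts agree with the reference implementation", {
  for (s in 1:5) {
    tr <- simulate_yule_tree(25, 0.2, seed = s)
    x <- setNames(rnorm(25), tr$tip.label)
    mine <- pic_contrasts(tr, x)
    ref <- ape::pic(x[tr$tip.label], tr)
    expect_equal(sort(abs(mine$contrast)), sort(abs(unname(ref))),
                 tolerance = 1e-10)
    expect_equal(nrow(mine), 24) # n - 1 contrasts
  }
})

test_that("contrast errors are informative", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_error(pic_contrasts(tr, c(A = 1, B = 2)), "no trait value")
  expect_error(pic_contrasts(tr, c(A = 1, B = NA, C = 2)), "missing")
  tr0 <- tr
  tr0$edge.length[1] <- 0
  expect_error(pic_contrasts(tr0, c(A = 1, B = 2, C = 3)), "non-positive")
})

test_that("through-origin correlation behaves and matches brute force", {
  x <- c(1.2, -0.5, 2, 0.3, -1.4)
  expect_equal(pic_correlation(x, 2 * x)$estimate, 1)
  res <- pic_correlation(x, -x)
  expect_equal(res$estimate, -1)
  expect_equal(pic_correlation(x, -x, method = "kendall")$estimate, -1)

  # independent recomputation of statistic and p at a realistic size
  set.seed(31)
  cx <- rnorm(29)
  cy <- 0.6 * cx + sqrt(1 - 0.36) * rnorm(29)
  res <- pic_correlation(cx, cy)
  r_direct <- as.numeric((cx %*% cy) /
                           sqrt((cx %*% cx) * (cy %*% cy)))
  expect_equal(res$estimate, r_direct, tolerance = 1e-12)
  t_direct <- r_direct * sqrt(28 / (1 - r_direct^2))
  expect_equal(res$p.value, 2 * pt(-abs(t_direct), 28), tolerance = 1e-12)

  expect_error(pic_correlation(x, x[1:3]), "length")
  expect_error(pic_correlation(rep(0, 5), x), "zero variance")
})

test_that("through-origin PIC slope equals the GLS slope", {
  for (s in 1:10) {
    n <- 4 + (s %% 9)
    tr <- simulate_yule_tree(n, 1, seed = 100 + s)
    tt <- simulate_bm_traits(tr, rho = 0.4, seed = 200 + s)
    x <- setNames(tt$trait1, tt$species)
    y <- setNames(tt$trait2, tt$species)
    cx <- pic_contrasts(tr, x)$contrast
    cy <- pic_contrasts(tr, y)$contrast
    expect_equal(sum(cx * cy) / sum(cx^2), gls_slope(tr, x, y),
                 tolerance = 1e-9)
  }
})

test_that("correlate_traits prunes to shared species (pairwise deletion)", {
  tr <- simulate_yule_tree(10, 0.5, seed = 4)
  tt <- simulate_bm_traits(tr, rho = 0, seed = 5)
  tt$trait1[c(1, 3)] <- NA
  res <- correlate_traits(tt, tr, "trait1", "trait2")
  expect_equal(res$n, 7) # 8 species remain -> 7 contrasts
  expect_s3_class(attr(res, "contrasts"), "tbl_df")
})

test_that("Cook's distance through the origin matches refit oracles", {
  # collinear points: all distances zero
  x <- c(1, 2, 3, 4)
  expect_equal(cooks_distance_origin(x, 3 * x)$cooks_d, rep(0, 4))

  # a gross outlier dominates
  x2 <- c(x, 2.5)
  y2 <- c(3 * x, 30)
  d <- cooks_distance_origin(x2, y2)
  expect_equal(which.max(d$cooks_d), 5)

  # matches stats::cooks.distance on the through-origin lm
  set.seed(9)
  xr <- rnorm(10)
  yr <- 1.5 * xr + rnorm(10, sd = 0.5)
  mine <- cooks_distance_origin(xr, yr)$cooks_d
  ref <- unname(stats::cooks.distance(lm(yr ~ xr + 0)))
  expect_equal(mine, ref, tolerance = 1e-9)

  # leave-one-out identity: D_i = (beta - beta_(-i))^2 * Sxx / s^2
  sxx <- sum(xr^2)
  beta <- sum(xr * yr) / sxx
  s2 <- sum((yr - beta * xr)^2) / 9
  loo <- vapply(1:10, function(i) {
    bi <- sum(xr[-i] * yr[-i]) / sum(xr[-i]^2)
    (beta - bi)^2 * sxx / s2
  }, numeric(1))
  expect_equal(mine, loo, tolerance = 1e-9)

  expect_error(cooks_distance_origin(rep(0, 5), rnorm(5)), "zero")
})

test_that("quartile bins split by type-7 quantiles with documented ties", {
  b <- quartile_bins(1:8)
  expect_equal(as.vector(table(b)), rep(2, 4))

  expect_warning(bq <- quartile_bins(rep(2, 6)), "collapse")
  expect_true(all(bq == "Q1"))

  expect_error(quartile_bins(c(1, 2, 3)), "at least 4")

  # published rates: smallest genome-wide rate lands in Q1, largest in Q4
  tt <- angiosperm_traits()
  bins <- quartile_bins(tt$recomb_rate_cM_Mb, labels = tt$species)
  expect_equal(as.character(bins[["Zea_mays"]]), "Q1")
  expect_equal(as.character(bins[["Brachypodium_distachyon"]]), "Q4")
})
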