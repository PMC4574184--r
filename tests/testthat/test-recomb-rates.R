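map_tbl <- function(lengths, markers, species = "sp", map_id = "m1") {
  tibble::tibble(
    species = species, map_id = map_id,
    linkage_group = seq_along(lengths),
    length_cM = lengths, n_markers = markers
  )
}

test_that("Chakravarti method-4 correction inflates by (m+1)/(m-1) per group", {
  expect_equal(correct_map_length(map_tbl(100, 11))$corrected_length_cM, 120)
  # correction vanishes with dense markers
  expect_equal(correct_map_length(map_tbl(100, 1e6))$corrected_length_cM,
               100, tolerance = 1e-5)
  # per-group factor, then sum
  expect_equal(
    correct_map_length(map_tbl(c(50, 50), c(3, 3)))$corrected_length_cM,
    200
  )
  expect_error(correct_map_length(map_tbl(100, 1)), "marker count")

  # monotone decreasing in m, always >= observed
  lens <- vapply(c(3, 5, 10, 50, 1000), function(m) {
    correct_map_length(map_tbl(100, m))$corrected_length_cM
  }, numeric(1))
  expect_true(all(diff(lens) < 0))
  expect_true(all(lens >= 100))
})

test_that("multiple maps are corrected first, then averaged", {
  one <- correct_map_length(map_tbl(100, 11))
  expect_equal(average_corrected_length(map_tbl(100, 11))$L_corr_cM, 120)
  two <- dplyr::bind_rows(
    map_tbl(100, 1e9, map_id = "a"), # corrected ~100
    map_tbl(70, 3, map_id = "b")     # corrected 140
  )
  expect_equal(average_corrected_length(two)$L_corr_cM, 120, tolerance = 1e-6)
  expect_error(average_corrected_length(map_tbl(10, 5)[0, ]), "empty")
})

test_that("rate arithmetic and unit identities hold", {
  # inputs chosen so the global rate reproduces the largest-genome species
  expect_equal(global_recomb_rate(0.72 * 2066.4, 2066.4), 0.72)
  expect_equal(global_recomb_rate(0, 100), 0)
  expect_equal(global_recomb_rate(500, 125), 4)
  expect_error(global_recomb_rate(10, 0), "positive")

  expect_equal(cvalue_recomb_rate(300, 1.5), 200)
  expect_equal(cvalue_recomb_rate(521, 0.521), 1000)
  expect_error(cvalue_recomb_rate(1, 0), "positive")

  expect_equal(genome_size_without_ltr(2066.4, 0.751), 514.5336)
  expect_equal(genome_size_without_ltr(100, 0), 100)
  expect_equal(genome_size_without_ltr(100, 1), 0)
  expect_error(genome_size_without_ltr(1, 1.2), "\\[0, 1\\]")

  expect_equal(gene_density(31114, 125), 248.912)
  expect_equal(gene_density(0, 10), 0)

  expect_equal(genome_compactness(125, 5), 25)
  expect_equal(genome_compactness(2066.4, 10), 206.64)
  expect_error(genome_compactness(10, 0), ">= 1")
})

test_that("euchromatin correction satisfies its ratio identity", {
  # h = 0.05 is the fixed point (0.95/0.95 = 1)
  expect_equal(euchromatin_recomb_rate(100, 50, 0.05),
               global_recomb_rate(100, 50))
  expect_equal(euchromatin_recomb_rate(100, 50, 0),
               0.95 * global_recomb_rate(100, 50))
  expect_error(euchromatin_recomb_rate(1, 1, 1), "\\[0, 1\\)")

  # rho_e * G * (1-h) = 0.95 * L for random valid inputs
  set.seed(42)
  for (i in 1:50) {
    L <- runif(1, 100, 3000)
    G <- runif(1, 100, 3000)
    h <- runif(1, 0, 0.95)
    rho_e <- euchromatin_recomb_rate(L, G, h)
    expect_equal(rho_e * G * (1 - h), 0.95 * L, tolerance = 1e-9)
  }

  # tomato: printed rate pair implies h ~ 0.77, which reproduces the pair
  h_tom <- implied_heterochromatin(1.81, 7.50)
  expect_equal(h_tom, 1 - 0.95 * 1.81 / 7.50)
  expect_equal(euchromatin_recomb_rate(1.81 * 760, 760, h_tom), 7.50,
               tolerance = 1e-9)
})

test_that("map screening rejects maps with wrong linkage-group counts", {
  maps <- dplyr::bind_rows(
    map_tbl(c(100, 90), c(10, 10), species = "a"),
    map_tbl(c(100, 90, 80), c(10, 10, 10), species = "b")
  )
  nchr <- tibble::tibble(species = c("a", "b"), n_chrom = c(2, 2))
  expect_warning(kept <- validate_genetic_maps(maps, nchr), "dropping")
  expect_equal(unique(kept$species), "a")
  expect_error(validate_genetic_maps(map_tbl(100, 1)), "fewer than 2")
})

test_that("trait-table assembly derives columns and propagates missingness", {
  profiles <- tibble::tibble(
    species = c("a", "b"),
    genome_size_Mb = c(200, 400),
    heterochromatin_fraction = c(0.2, NA),
    ltr_proportion = c(0.1, 0.5),
    predicted_gene_count = c(20000, NA),
    n_chrom = c(5, 8)
  )
  maps <- dplyr::bind_rows(
    map_tbl(c(100, 120), c(11, 11), species = "a"),
    map_tbl(c(200, 150), c(21, 21), species = "b")
  )
  tt <- build_trait_table(profiles, maps)
  expect_equal(nrow(tt), 2)
  expect_equal(tt$L_corr_cM[1], (100 + 120) * 12 / 10)
  expect_equal(tt$recomb_rate_cM_Mb, tt$L_corr_cM / tt$genome_size_Mb)
  # h missing => euchromatin rate missing, others present
  expect_true(is.na(tt$euchromatin_rate_cM_Mb[2]))
  expect_false(is.na(tt$genome_size_no_ltr_Mb[2]))
  expect_true(is.na(tt$gene_density_per_Mb[2]))
  expect_equal(tt$compactness_Mb_per_chrom, c(40, 50))
  expect_error(
    build_trait_table(profiles[1, ], maps),
    "no profile"
  )
})

test_that("bundled angiosperm trait table is internally consistent", {
  tt <- angiosperm_traits()
  expect_equal(nrow(tt), 30)
  expect_equal(sum(!is.na(tt$euchromatin_rate_cM_Mb)), 19)
  # copia + gypsy never exceeds the total LTR proportion... except where
  # sub-family surveys used different denominators; all proportions valid
  expect_true(all(tt$ltr_proportion >= 0 & tt$ltr_proportion <= 1,
                  na.rm = TRUE))
  both <- !is.na(tt$euchromatin_rate_cM_Mb)
  h <- implied_heterochromatin(tt$recomb_rate_cM_Mb[both],
                               tt$euchromatin_rate_cM_Mb[both])
  expect_true(all(h > 0 & h < 1))
})
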