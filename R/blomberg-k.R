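#' Blomberg's K statistic of phylogenetic signal
#'
#' K compares the mean squared error of tip values around the phylogenetic
#' mean (MSE0) with the phylogenetically corrected mean squared error (MSE),
#' scaled by the ratio expected under Brownian motion on the given tree:
#' \deqn{K = \frac{MSE_0/MSE}{\left[\mathrm{tr}(V) - n/(\mathbf{1}'V^{-1}
#' \mathbf{1})\right]/(n-1)}}
#' with \eqn{V} the phylogenetic covariance matrix and the phylogenetic mean
#' \eqn{\hat a = (\mathbf{1}'V^{-1}x)/(\mathbf{1}'V^{-1}\mathbf{1})}. K is 1
#' in expectation under Brownian motion; larger values indicate stronger
#' clustering of trait values on the tree, smaller values overdispersion. K
#' is invariant to affine transforms of the trait.
#'
#' @param tree A strictly binary, rooted `"phylo"` object.
#' @param x Named numeric tip values, or data frame with `species` column.
#' @param trait Column name when `x` is a data frame.
#' @return An object of class `"recombevol_k"`: list with `K`,
#'   `observed_ratio` (MSE0/MSE), `expected_ratio`, `n`, and (after
#'   [blomberg_k_test()]) `p.value`, `reps`, `permuted` statistics.
#' @export
blomberg_k <- function(tree, x, trait = NULL) {
  validate_phylo(tree, require_binary = TRUE)
  if (is.data.frame(x)) {
    if (is.null(trait)) abort("supply `trait` when `x` is a data frame")
    x <- setNames(x[[trait]], x$species)
  }
  vals <- as.numeric(x[tree$tip.label])
  if (anyNA(vals)) abort("missing trait value at a tip")
  n <- length(vals)
  if (n < 2) abort("need at least 2 tips")
  V <- phylo_vcv(tree)
  Vi <- tryCatch(solve(V), error = function(e) {
    abort("phylogenetic covariance matrix is singular")
  })
  one <- rep(1, n)
  denom1 <- as.numeric(one %*% Vi %*% one)
  a_hat <- as.numeric(one %*% Vi %*% vals) / denom1
  dev <- vals - a_hat
  mse0 <- sum(dev^2)
  mse <- as.numeric(dev %*% Vi %*% dev)
  observed <- mse0 / mse
  expected <- (sum(diag(V)) - n / denom1) / (n - 1)
  structure(
    list(K = observed / expected, observed_ratio = observed,
         expected_ratio = expected, n = n, p.value = NA_real_,
         reps = 0L),
    class = "recombevol_k"
  )
}

#' Permutation test for phylogenetic signal
#'
#' Computes Blomberg's K and its significance from random permutations of
#' the tip values over the phylogeny. The permutation statistic is the
#' variance of the standardised independent contrasts (a trait with true
#' signal yields lower contrast variance than tip-shuffled data); the
#' p-value is \eqn{(1 + \#\{\mathrm{perm} \le \mathrm{obs}\})/(reps+1)}.
#' Setting `statistic = "K"` permutes on K itself (upper tail) instead.
#'
#' @inheritParams blomberg_k
#' @param reps Number of permutations (default 999).
#' @param seed Integer seed; results are reproducible given the seed.
#' @param statistic `"contrast_variance"` (default) or `"K"`.
#' @return A `"recombevol_k"` object with `p.value`, `reps`, and the
#'   observed permutation statistic `stat`.
#' @export
blomberg_k_test <- function(tree, x, trait = NULL, reps = 999, seed = NULL,
                            statistic = c("contrast_variance", "K")) {
  statistic <- match.arg(statistic)
  if (reps < 1) abort("reps must be >= 1")
  res <- blomberg_k(tree, x, trait = trait)
  if (res$n < 3) abort("permutation test needs at least 3 tips")
  if (is.data.frame(x)) x <- setNames(x[[trait]], x$species)
  vals <- as.numeric(x[tree$tip.label])
  n <- length(vals)

  if (statistic == "contrast_variance") {
    # contrasts are linear in the tip values: precompute the operator once,
    # then each permutation is a matrix product
    C <- pic_linear_operator(tree)
    obs <- var(as.numeric(C %*% vals))
    perms <- with_seed(seed, {
      replicate(reps, vals[sample.int(n)])
    })
    perm_stat <- apply(C %*% perms, 2, var)
    p <- (1 + sum(perm_stat <= obs)) / (reps + 1)
  } else {
    V <- phylo_vcv(tree)
    Vi <- solve(V)
    one <- rep(1, n)
    denom1 <- as.numeric(one %*% Vi %*% one)
    expected <- (sum(diag(V)) - n / denom1) / (n - 1)
    k_of <- function(v) {
      a <- as.numeric(one %*% Vi %*% v) / denom1
      d <- v - a
      (sum(d^2) / as.numeric(d %*% Vi %*% d)) / expected
    }
    obs <- res$K
    perm_stat <- with_seed(seed, {
      replicate(reps, k_of(vals[sample.int(n)]))
    })
    p <- (1 + sum(perm_stat >= obs)) / (reps + 1)
  }
  res$p.value <- p
  res$reps <- as.integer(reps)
  res$stat <- obs
  res$statistic <- statistic
  res$permuted <- perm_stat
  res
}

#' @export
print.recombevol_k <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4f (n = %d tips)\n", x$K, x$n))
  if (!is.na(x$p.value)) {
    cat(sprintf("  permutation p = %.4g (%d permutations, %s statistic)\n",
                x$p.value, x$reps, x$statistic))
  }
  invisible(x)
}

#' Phylogenetic-signal table for several traits
#'
#' Runs [blomberg_k_test()] on each requested column of a species trait
#' table, pruning the tree to the species with data for each trait.
#'
#' @param traits Data frame with a `species` column.
#' @param tree `"phylo"` object covering the species.
#' @param columns Character vector of trait columns (default: all numeric).
#' @param reps,seed Passed to [blomberg_k_test()].
#' @return Tibble with `trait`, `n`, `K`, `p.value`.
#' @export
phylo_signal_table <- function(traits, tree, columns = NULL, reps = 999,
                               seed = NULL) {
  if (is.null(columns)) {
    columns <- names(traits)[vapply(traits, is.numeric, logical(1))]
  }
  purrr::map_dfr(seq_along(columns), function(i) {
    col <- columns[i]
    keep <- traits$species[!is.na(traits[[col]])]
    keep <- intersect(tree$tip.label, keep)
    if (length(keep) < 3) {
      return(tibble(trait = col, n = length(keep), K = NA_real_,
                    p.value = NA_real_))
    }
    tr <- if (length(keep) < ape::Ntip(tree)) {
      ape::drop.tip(tree, setdiff(tree$tip.label, keep))
    } else {
      tree
    }
    v <- setNames(traits[[col]][match(keep, traits$species)], keep)
    kt <- blomberg_k_test(tr, v, reps = reps,
                          seed = if (is.null(seed)) NULL else sub_seed(seed, i))
    tibble(trait = col, n = kt$n, K = kt$K, p.value = kt$p.value)
  })
}
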