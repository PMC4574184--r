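#' Fixed-effects meta-analysis of correlation coefficients
#'
#' Pools study correlations on the Fisher-z scale with inverse-variance
#' (fixed-effects) weights \eqn{w_i = n_i - 3}: pooled
#' \eqn{\bar z = \sum w_i z_i / \sum w_i}, standard error
#' \eqn{1/\sqrt{\sum w_i}}, back-transformed estimate
#' \eqn{\tanh(\bar z)} with a normal confidence interval on the z scale,
#' and a two-sided p-value from \eqn{\bar z/SE}.
#'
#' @param studies Data frame with columns `r` (each `|r| < 1`) and `n`
#'   (each `>= 4`), one row per study.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `"recombevol_metacor"`: list with `r`
#'   (pooled), `ci_low`, `ci_high`, `z`, `se`, `p.value`, `k` (study
#'   count). `tidy()`/`glance()` methods available.
#' @examples
#' metacor_fixed(tibble::tibble(r = c(0.5, 0.6), n = c(30, 40)))
#' @export
metacor_fixed <- function(studies, conf_level = 0.95) {
  if (!all(c("r", "n") %in% names(studies))) {
    abort("`studies` needs columns `r` and `n`")
  }
  r <- studies$r
  n <- studies$n
  if (any(abs(r) >= 1)) abort("every |r| must be < 1")
  if (any(n < 4)) abort("every study n must be >= 4 (weights n - 3)")
  z <- atanh(r)
  w <- n - 3
  zbar <- sum(w * z) / sum(w)
  se <- 1 / sqrt(sum(w))
  crit <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      r = tanh(zbar),
      ci_low = tanh(zbar - crit * se),
      ci_high = tanh(zbar + crit * se),
      z = zbar, se = se,
      p.value = 2 * pnorm(-abs(zbar / se)),
      k = length(r), conf_level = conf_level
    ),
    class = "recombevol_metacor"
  )
}

#' @export
print.recombevol_metacor <- function(x, ...) {
  cat(sprintf(
    "Fixed-effects metacorrelation: r = %.3f, %g%% CI (%.3f, %.3f), p = %.3g (k = %d)\n",
    x$r, 100 * x$conf_level, x$ci_low, x$ci_high, x$p.value, x$k
  ))
  invisible(x)
}

#' Ploidy-resampling metacorrelation of recombination rate and genome size
#'
#' Species can carry several C-values (haploid DNA contents) reflecting
#' different ploidy levels. To test whether ploidy choice drives the
#' recombination-rate/genome-size association, this resamples one C-value
#' per species, recomputes the cM/pg recombination rate, runs
#' phylogenetically corrected correlations of that rate against genome size
#' in pg and in Mb, and pools the replicate correlations by fixed-effects
#' meta-analysis. The study size for each replicate is the species count
#' (contrast count + 1).
#'
#' @param tree A strictly binary `"phylo"` object covering the species.
#' @param lengths Data frame with `species` and `L_corr_cM` (corrected map
#'   lengths, e.g. from [average_corrected_length()]).
#' @param c_values Data frame with `species` and `c_value_pg`; species may
#'   repeat with distinct C-values.
#' @param genome_sizes Data frame with `species` and `genome_size_Mb`.
#' @param n_datasets Number of resampled datasets (default 100).
#' @param seed Integer seed (replicate streams derived by counter).
#' @param log10_branches Passed to [correlate_traits()].
#' @return A list with elements `vs_pg` and `vs_Mb`, each a
#'   `"recombevol_metacor"`, plus `replicates`, a tibble of per-replicate
#'   correlations.
#' @export
ploidy_metacorrelation <- function(tree, lengths, c_values, genome_sizes,
                                   n_datasets = 100, seed = NULL,
                                   log10_branches = FALSE) {
  sp <- intersect(tree$tip.label, lengths$species)
  no_cv <- setdiff(sp, c_values$species)
  if (length(no_cv) > 0) {
    abort(paste0("species lacking a C-value: ", paste(no_cv, collapse = ", ")))
  }
  cv_by_sp <- split(c_values$c_value_pg, c_values$species)

  one_rep <- function(i) {
    pg <- with_seed(
      if (is.null(seed)) NULL else sub_seed(seed, i),
      vapply(sp, function(s) {
        v <- cv_by_sp[[s]]
        if (length(v) == 1) v else sample(v, 1)
      }, numeric(1))
    )
    df <- tibble(
      species = sp,
      rate_cM_pg = cvalue_recomb_rate(
        lengths$L_corr_cM[match(sp, lengths$species)], pg
      ),
      size_pg = pg,
      size_Mb = genome_sizes$genome_size_Mb[
        match(sp, genome_sizes$species)
      ]
    )
    r_pg <- correlate_traits(df, tree, "rate_cM_pg", "size_pg",
                             log10_branches = log10_branches)
    r_mb <- correlate_traits(df, tree, "rate_cM_pg", "size_Mb",
                             log10_branches = log10_branches)
    tibble(replicate = i, r_vs_pg = r_pg$estimate, r_vs_Mb = r_mb$estimate,
           n = r_pg$n + 1)
  }
  reps <- purrr::map_dfr(seq_len(n_datasets), one_rep)
  list(
    vs_pg = metacor_fixed(tibble(r = reps$r_vs_pg, n = reps$n)),
    vs_Mb = metacor_fixed(tibble(r = reps$r_vs_Mb, n = reps$n)),
    replicates = reps
  )
}
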