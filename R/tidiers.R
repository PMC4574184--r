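#' Tidy a contrast correlation
#'
#' @param x A `"recombevol_cor"` object.
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `statistic`, `p.value`, `n`,
#'   `method`.
#' @export
tidy.recombevol_cor <- function(x, ...) {
  tibble(estimate = x$estimate, statistic = x$statistic,
         p.value = x$p.value, n = x$n, method = x$method)
}

#' @rdname tidy.recombevol_cor
#' @export
glance.recombevol_cor <- function(x, ...) tidy(x)

#' Tidy a Blomberg's K result
#'
#' @param x A `"recombevol_k"` object.
#' @param ... Unused.
#' @return One-row tibble: `K`, `observed_ratio`, `expected_ratio`, `n`,
#'   `p.value`, `reps`.
#' @export
tidy.recombevol_k <- function(x, ...) {
  tibble(K = x$K, observed_ratio = x$observed_ratio,
         expected_ratio = x$expected_ratio, n = x$n,
         p.value = x$p.value, reps = x$reps)
}

#' @rdname tidy.recombevol_k
#' @export
glance.recombevol_k <- function(x, ...) tidy(x)

#' Tidy a fixed-effects metacorrelation
#'
#' @param x A `"recombevol_metacor"` object.
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `ci_low`, `ci_high`, `z`, `se`,
#'   `p.value`, `k`.
#' @export
tidy.recombevol_metacor <- function(x, ...) {
  tibble(estimate = x$r, ci_low = x$ci_low, ci_high = x$ci_high,
         z = x$z, se = x$se, p.value = x$p.value, k = x$k)
}

#' @rdname tidy.recombevol_metacor
#' @export
glance.recombevol_metacor <- function(x, ...) tidy(x)

#' Tidy a coevolution screen
#'
#' @param x A `"recombevol_screen"` object.
#' @param ... Unused.
#' @return Tibble of the four significance-by-sign counts.
#' @export
tidy.recombevol_screen <- function(x, ...) {
  tibble(
    class = c("neg_sig", "pos_sig", "neg_nonsig", "pos_nonsig"),
    count = c(x$counts$neg_sig, x$counts$pos_sig,
              x$counts$neg_nonsig, x$counts$pos_nonsig)
  )
}

#' @rdname tidy.recombevol_screen
#' @param ... Unused.
#' @export
glance.recombevol_screen <- function(x, ...) {
  tibble(
    cutoff = x$cutoff,
    realized_fraction = x$realized_fraction,
    nominal_fraction = x$nominal_fraction,
    n_converged = x$n_converged,
    n_dropped = x$n_dropped,
    chisq = x$chisq$statistic,
    chisq_p = x$chisq$p.value
  )
}
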