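#' Plot contrast pairs with the through-origin fit
#'
#' Scatter of the standardised contrast pairs behind a correlation from
#' [correlate_traits()], with the through-origin least-squares line.
#'
#' @param object A `"recombevol_cor"` from [correlate_traits()] (must carry
#'   the `"contrasts"` attribute).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recombevol_cor <- function(object, ...) {
  cs <- attr(object, "contrasts")
  if (is.null(cs)) abort("no contrast pairs attached; use correlate_traits()")
  nm <- attr(object, "traits")
  slope <- sum(cs$contrast_x * cs$contrast_y) / sum(cs$contrast_x^2)
  ggplot2::ggplot(cs, ggplot2::aes(x = .data$contrast_x,
                                   y = .data$contrast_y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = slope, linetype = 2) +
    ggplot2::labs(
      x = paste("contrasts:", nm[["x"]]),
      y = paste("contrasts:", nm[["y"]]),
      title = sprintf("r = %.2f (p = %.3g, k = %d)",
                      object$estimate, object$p.value, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the permutation null of a phylogenetic-signal test
#'
#' Histogram of the permuted statistic with the observed value marked.
#'
#' @param object A `"recombevol_k"` from [blomberg_k_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recombevol_k <- function(object, ...) {
  if (is.null(object$permuted)) abort("run blomberg_k_test() first")
  df <- tibble(stat = object$permuted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$stat, colour = "red") +
    ggplot2::labs(
      x = paste("permutation statistic:", object$statistic),
      y = "permutations",
      title = sprintf("K = %.2f, p = %.3g (%d permutations)",
                      object$K, object$p.value, object$reps)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the posterior-probability landscape of a coevolution screen
#'
#' Histogram of per-gene posterior probabilities with the calibrated
#' cutoffs marked; significant tails are shaded.
#'
#' @param object A `"recombevol_screen"` from [coevol_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recombevol_screen <- function(object, ...) {
  df <- object$records
  df$significant <- df$pp <= object$cutoff | df$pp >= 1 - object$cutoff
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pp, fill = .data$significant)) +
    ggplot2::geom_histogram(bins = 50, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(object$cutoff, 1 - object$cutoff),
                        linetype = 2) +
    ggplot2::scale_fill_manual(values = c("grey70", "firebrick")) +
    ggplot2::labs(
      x = "posterior probability of positive correlation",
      y = "genes",
      title = sprintf("calibrated cutoffs %.3f / %.3f (%.1f%% significant)",
                      object$cutoff, 1 - object$cutoff,
                      100 * object$realized_fraction)
    ) +
    ggplot2::theme_minimal()
}

#' Quartile-binned trait distributions
#'
#' Boxplots of a per-species value (e.g. mean ENC or GC3s) grouped by
#' quartile bins of another trait (e.g. recombination rate).
#'
#' @param data Data frame with a `species` column.
#' @param bin_by Column to bin into quartiles.
#' @param value Column to summarise within bins.
#' @return A ggplot object.
#' @export
plot_quartile_distributions <- function(data, bin_by, value) {
  ok <- !is.na(data[[bin_by]]) & !is.na(data[[value]])
  df <- data[ok, ]
  df$bin <- quartile_bins(df[[bin_by]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data[[value]])) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = paste(bin_by, "quartile"), y = value) +
    ggplot2::theme_minimal()
}
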