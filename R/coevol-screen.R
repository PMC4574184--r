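#' Filter coevolution gene records on MCMC convergence
#'
#' Keeps genes whose chains converged: minimum effective sample size over
#' all parameters strictly greater than `ess_min`, and root-ancestral-state
#' ESS strictly greater than `root_ess_min` (the root state mixes slowly
#' over deep timescales, so it gets its own laxer bar).
#'
#' @param records Tibble with at least `min_ess` and `root_ess` columns.
#' @param ess_min ESS threshold for all parameters (default 300).
#' @param root_ess_min ESS threshold for the root state (default 50).
#' @return The filtered tibble, with attribute `"convergence"` = list of
#'   `kept` and `dropped` counts.
#' @export
convergence_filter <- function(records, ess_min = 300, root_ess_min = 50) {
  if (!all(c("min_ess", "root_ess") %in% names(records))) {
    abort("`records` needs columns min_ess and root_ess")
  }
  if (anyNA(records$min_ess) || anyNA(records$root_ess)) {
    abort("missing ESS values")
  }
  keep <- records$min_ess > ess_min & records$root_ess > root_ess_min
  out <- records[keep, ]
  attr(out, "convergence") <- list(kept = sum(keep), dropped = sum(!keep))
  out
}

#' Calibrate symmetric posterior-probability cutoffs
#'
#' Posterior probabilities are not p-values, so family-wise or FDR
#' corrections do not apply; instead the nominal two-tailed cutoffs are
#' tightened until at most a target fraction of genes is called
#' significant. Finds the largest symmetric cutoff `c` in `(0, 0.5)` such
#' that the fraction of genes with `pp <= c` or `pp >= 1 - c` (boundary
#' genes included) does not exceed `target_fraction`.
#'
#' Tie rules: `c` is reported as the largest observed tail distance
#' `min(pp, 1 - pp)` that satisfies the bound (the realized fraction is a
#' step function, so any value up to the next observed distance gives the
#' same calls). If no gene has `pp != 0.5`, no tail exists below 0.5 and
#' `c = 0.5 - 1e-9` with realized fraction 0. If even the smallest
#' achievable nonzero fraction exceeds the target, `c = 0` is returned with
#' a warning.
#'
#' @param pps Numeric vector of posterior probabilities in `[0, 1]`.
#' @param target_fraction Target significant fraction (default 0.05).
#' @return A list with `cutoff`, `realized_fraction`, `n_significant`, `n`.
#' @examples
#' calibrate_pp_cutoffs(seq_len(2000) / 2001)
#' @export
calibrate_pp_cutoffs <- function(pps, target_fraction = 0.05) {
  if (length(pps) < 1) abort("need at least one posterior probability")
  if (any(pps < 0 | pps > 1)) abort("posterior probabilities must lie in [0, 1]")
  if (target_fraction <= 0 || target_fraction >= 1) {
    abort("target fraction must lie in (0, 1)")
  }
  n <- length(pps)
  # snap to 12 decimals so pp and 1 - pp land on the same tail distance
  # (floating point would otherwise break the cutoff's symmetry)
  d <- round(pmin(pps, 1 - pps), 12)
  cand <- sort(unique(d[d < 0.5]))
  if (length(cand) == 0) {
    return(list(cutoff = 0.5 - 1e-9, realized_fraction = 0,
                n_significant = 0L, n = n))
  }
  frac <- vapply(cand, function(cc) mean(d <= cc), numeric(1))
  ok <- which(frac <= target_fraction)
  if (length(ok) == 0) {
    warn("target fraction unachievable: smallest tail already exceeds it")
    return(list(cutoff = 0, realized_fraction = mean(d <= 0),
                n_significant = sum(d <= 0), n = n))
  }
  cc <- cand[max(ok)]
  list(cutoff = cc, realized_fraction = frac[max(ok)],
       n_significant = as.integer(round(frac[max(ok)] * n)), n = n)
}

#' Classify genes by significance and correlation sign
#'
#' With calibrated cutoff `c`: significant-negative if `pp <= c`,
#' significant-positive if `pp >= 1 - c`, otherwise nonsignificant and
#' split by the sign of the correlation coefficient.
#'
#' @param records Tibble with columns `pp` and `correlation`.
#' @param cutoff Calibrated symmetric cutoff.
#' @return A list of counts: `neg_sig`, `pos_sig`, `neg_nonsig`,
#'   `pos_nonsig`, plus the classified tibble under `records` (new column
#'   `class`).
#' @export
classify_and_count <- function(records, cutoff) {
  if (!all(c("pp", "correlation") %in% names(records))) {
    abort("`records` needs columns pp and correlation")
  }
  cl <- dplyr::case_when(
    records$pp <= cutoff ~ "neg_sig",
    records$pp >= 1 - cutoff ~ "pos_sig",
    records$correlation < 0 ~ "neg_nonsig",
    TRUE ~ "pos_nonsig"
  )
  records$class <- factor(cl, levels = c("neg_sig", "pos_sig",
                                         "neg_nonsig", "pos_nonsig"))
  counts <- as.list(table(records$class))
  c(lapply(counts, as.integer), list(records = records))
}

#' Chi-square test on correlation sign counts
#'
#' Tests whether negative correlations (recombination associated with
#' stronger purifying selection) outnumber positive ones.
#' `mode = "gof_pooled"` pools significant and nonsignificant genes and
#' tests the (negative, positive) totals against 50:50;
#' `mode = "independence"` is the 2x2 Pearson test of significance x sign
#' (no continuity correction).
#'
#' @param counts List with `neg_sig`, `pos_sig`, `neg_nonsig`,
#'   `pos_nonsig` (as from [classify_and_count()]).
#' @param mode `"gof_pooled"` (default) or `"independence"`.
#' @return A list with `statistic`, `df`, `p.value`, `mode`.
#' @export
sign_chisq <- function(counts, mode = c("gof_pooled", "independence")) {
  mode <- match.arg(mode)
  neg <- counts$neg_sig + counts$neg_nonsig
  pos <- counts$pos_sig + counts$pos_nonsig
  if (mode == "gof_pooled") {
    if (neg + pos == 0) abort("no genes to test")
    ht <- chisq.test(c(neg, pos), p = c(0.5, 0.5))
  } else {
    tab <- matrix(c(counts$neg_sig, counts$pos_sig,
                    counts$neg_nonsig, counts$pos_nonsig),
                  nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      abort("zero expected cell in 2x2 table")
    }
    ht <- chisq.test(tab, correct = FALSE)
  }
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, mode = mode)
}

#' Two-sided Fisher exact test for annotation enrichment
#'
#' Tests whether an annotation class (e.g. zinc fingers, meiotic
#' recombination proteins) is over-represented among significant genes.
#' Two-sided p by summing hypergeometric probabilities of tables at most as
#' probable as the observed one.
#'
#' @param in_class_sig,in_class_nonsig,out_class_sig,out_class_nonsig
#'   Nonnegative cell counts of the 2x2 table.
#' @return The two-sided p-value.
#' @export
enrichment_fisher <- function(in_class_sig, in_class_nonsig,
                              out_class_sig, out_class_nonsig) {
  cells <- c(in_class_sig, in_class_nonsig, out_class_sig, out_class_nonsig)
  if (any(cells < 0)) abort("negative count")
  if (sum(cells) < 1) abort("empty table")
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  fisher.test(tab, alternative = "two.sided")$p.value
}

#' Full coevolution screen
#'
#' Convergence-filters per-gene coevolution records, calibrates the
#' posterior-probability cutoffs to the target significant fraction (also
#' reporting the nominal 0.025/0.975 fraction), classifies genes by
#' significance and sign, and runs the sign chi-square. Annotation
#' enrichment can then be tested per tag with [enrichment_fisher()].
#'
#' @param records Tibble with `gene`, `correlation`, `pp`, `min_ess`,
#'   `root_ess` (and optionally `tags`).
#' @param target_fraction Target significant fraction (default 0.05).
#' @param ess_min,root_ess_min Passed to [convergence_filter()].
#' @param chisq_mode Passed to [sign_chisq()].
#' @return An object of class `"recombevol_screen"`: list with `cutoff`,
#'   `realized_fraction`, `nominal_fraction` (at 0.025/0.975), counts,
#'   `chisq`, `n_converged`, `n_dropped`, and the classified `records`.
#' @export
coevol_screen <- function(records, target_fraction = 0.05,
                          ess_min = 300, root_ess_min = 50,
                          chisq_mode = "gof_pooled") {
  conv <- convergence_filter(records, ess_min, root_ess_min)
  meta <- attr(conv, "convergence")
  if (nrow(conv) == 0) abort("no converged genes")
  cal <- calibrate_pp_cutoffs(conv$pp, target_fraction)
  cls <- classify_and_count(conv, cal$cutoff)
  chs <- sign_chisq(cls, mode = chisq_mode)
  structure(
    list(
      cutoff = cal$cutoff,
      realized_fraction = cal$realized_fraction,
      nominal_fraction = mean(conv$pp <= 0.025 | conv$pp >= 0.975),
      target_fraction = target_fraction,
      counts = cls[c("neg_sig", "pos_sig", "neg_nonsig", "pos_nonsig")],
      chisq = chs,
      n_converged = meta$kept,
      n_dropped = meta$dropped,
      records = cls$records
    ),
    class = "recombevol_screen"
  )
}

#' @export
print.recombevol_screen <- function(x, ...) {
  cat("Coevolution screen\n")
  cat(sprintf("  converged genes: %d (dropped %d)\n",
              x$n_converged, x$n_dropped))
  cat(sprintf("  calibrated cutoffs: pp < %.4g or pp > %.4g\n",
              x$cutoff, 1 - x$cutoff))
  cat(sprintf("  significant fraction: %.3f realized (target %.3f; %.3f at nominal 0.025/0.975)\n",
              x$realized_fraction, x$target_fraction, x$nominal_fraction))
  ns <- x$counts$neg_sig
  ps <- x$counts$pos_sig
  if (ns + ps > 0) {
    cat(sprintf("  significant pool: %d negative (%.0f%%), %d positive (%.0f%%)\n",
                ns, 100 * ns / (ns + ps), ps, 100 * ps / (ns + ps)))
  }
  cat(sprintf("  sign chi-square (%s): X2 = %.2f, p = %.3g\n",
              x$chisq$mode, x$chisq$statistic, x$chisq$p.value))
  invisible(x)
}
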