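#' Phylogenetic independent contrasts
#'
#' Felsenstein's recursion: at each internal node of a strictly binary tree
#' with child values \eqn{x_1, x_2} on working branch lengths
#' \eqn{v_1, v_2}, the standardised contrast is
#' \eqn{(x_1 - x_2)/\sqrt{v_1 + v_2}}; the node is assigned the working
#' value \eqn{(x_1/v_1 + x_2/v_2)/(1/v_1 + 1/v_2)} and its stem branch is
#' lengthened by \eqn{v_1 v_2/(v_1 + v_2)}. Under Brownian motion the n-1
#' contrasts are independent with unit variance, so ordinary (through-origin)
#' correlation and regression apply to cross-species data.
#'
#' Contrasts are returned in deterministic postorder; the contrast at a node
#' subtracts the second child (in edge order) from the first, matching the
#' convention of [ape::pic()].
#'
#' @param tree A strictly binary, rooted `"phylo"` object with positive
#'   branch lengths (apply [log10_branch_transform()] first if desired).
#' @param x Named numeric vector of tip values (names = tip labels), or a
#'   data frame with columns `species` and the trait named by `trait`.
#' @param trait Column name when `x` is a data frame.
#' @return A tibble with one row per internal node: `node` (ape node id),
#'   `contrast` (standardised), `sum_v` (the variance
#'   \eqn{v_1 + v_2} of the raw contrast). The ancestral working values are
#'   attached as attribute `"node_values"`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' pic_contrasts(tr, c(A = 1, B = 3, C = 4))
#' @export
pic_contrasts <- function(tree, x, trait = NULL) {
  validate_phylo(tree, require_binary = TRUE)
  if (is.data.frame(x)) {
    if (is.null(trait)) abort("supply `trait` when `x` is a data frame")
    x <- setNames(x[[trait]], x$species)
  }
  n <- ape::Ntip(tree)
  missing_tips <- setdiff(tree$tip.label, names(x))
  if (length(missing_tips) > 0) {
    abort(paste0("no trait value for tip(s): ",
                 paste(head(missing_tips, 5), collapse = ", ")))
  }
  vals <- as.numeric(x[tree$tip.label])
  if (anyNA(vals)) abort("missing trait value at a tip")
  if (any(tree$edge.length <= 0)) {
    abort("non-positive branch length: contrasts cannot be standardised")
  }

  ord <- ape::reorder.phylo(tree, "postorder")
  nv <- c(vals, rep(NA_real_, tree$Nnode)) # working values, ape numbering
  bl <- numeric(n + tree$Nnode)            # working branch lengths
  bl[ord$edge[, 2]] <- ord$edge.length
  contrast <- rep(NA_real_, tree$Nnode)
  sum_v <- rep(NA_real_, tree$Nnode)

  # parents in order of first appearance in the postorder edge list are
  # themselves in postorder (children always resolved first)
  parents <- unique(ord$edge[, 1])
  kids <- split(ord$edge[, 2], factor(ord$edge[, 1], levels = parents))
  for (par in parents) {
    ch <- kids[[as.character(par)]]
    c1 <- ch[1]
    c2 <- ch[2]
    v1 <- bl[c1]
    v2 <- bl[c2]
    i <- par - n
    contrast[i] <- (nv[c1] - nv[c2]) / sqrt(v1 + v2)
    sum_v[i] <- v1 + v2
    nv[par] <- (nv[c1] / v1 + nv[c2] / v2) / (1 / v1 + 1 / v2)
    bl[par] <- bl[par] + v1 * v2 / (v1 + v2)
  }

  out <- tibble(
    node = n + seq_len(tree$Nnode),
    contrast = contrast,
    sum_v = sum_v
  )
  # report in the postorder in which nodes were resolved
  out <- out[match(parents, out$node), ]
  attr(out, "node_values") <- setNames(
    nv[(n + 1):(n + tree$Nnode)], (n + 1):(n + tree$Nnode)
  )
  out
}

# (n-1) x n matrix C with C %*% x[tip.label] = contrasts, exploiting the
# linearity of the contrast recursion in the tip values. Used to make
# permutation tests cheap.
pic_linear_operator <- function(tree) {
  n <- ape::Ntip(tree)
  basis <- diag(n)
  rownames(basis) <- tree$tip.label
  cols <- lapply(seq_len(n), function(j) {
    pic_contrasts(tree, setNames(basis[, j], tree$tip.label))$contrast
  })
  C <- do.call(cbind, cols)
  colnames(C) <- tree$tip.label
  C
}

#' Correlation of independent contrasts
#'
#' Contrasts have an arbitrary sign, so their association is measured
#' through the origin: \eqn{r = \sum x_i y_i / \sqrt{\sum x_i^2 \sum
#' y_i^2}}, with a two-sided p-value from \eqn{t = r\sqrt{(k-1)/(1-r^2)}} on
#' `k - 1` degrees of freedom (`k` contrasts). A non-origin Pearson and a
#' Kendall tau option (robust to outlying contrasts) are provided for
#' sensitivity analysis.
#'
#' @param cs_x,cs_y Contrast tibbles from [pic_contrasts()] on the same
#'   tree (or plain numeric vectors of equal length).
#' @param method `"pearson_origin"` (default), `"pearson"`, or
#'   `"kendall"` (tau-b; exact p for 10 or fewer pairs, normal
#'   approximation above).
#' @return An object of class `"recombevol_cor"`: a list with `estimate`,
#'   `statistic`, `p.value`, `n` (number of contrast pairs), `method`.
#'   `tidy()` and `glance()` methods are available.
#' @export
pic_correlation <- function(cs_x, cs_y,
                            method = c("pearson_origin", "pearson",
                                       "kendall")) {
  method <- match.arg(method)
  x <- if (is.data.frame(cs_x)) cs_x$contrast else as.numeric(cs_x)
  y <- if (is.data.frame(cs_y)) cs_y$contrast else as.numeric(cs_y)
  if (is.data.frame(cs_x) && is.data.frame(cs_y) &&
      !identical(cs_x$node, cs_y$node)) {
    abort("contrast sets come from different trees or node orders")
  }
  if (length(x) != length(y)) abort("contrast sets differ in length")
  k <- length(x)
  if (k < 3) abort("need at least 3 contrast pairs")
  if (sum(x^2) == 0 || sum(y^2) == 0) abort("zero variance in contrasts")

  if (method == "pearson_origin") {
    r <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    tstat <- r * sqrt((k - 1) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = k - 1)
    out <- list(estimate = r, statistic = tstat, p.value = p, n = k,
                method = method)
  } else if (method == "pearson") {
    ct <- stats::cor.test(x, y, method = "pearson")
    out <- list(estimate = unname(ct$estimate),
                statistic = unname(ct$statistic),
                p.value = ct$p.value, n = k, method = method)
  } else {
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "kendall", exact = k <= 10)
    )
    out <- list(estimate = unname(ct$estimate),
                statistic = unname(ct$statistic),
                p.value = ct$p.value, n = k, method = method)
  }
  structure(out, class = "recombevol_cor")
}

#' @export
print.recombevol_cor <- function(x, ...) {
  cat("Contrast correlation (", x$method, ")\n", sep = "")
  cat(sprintf("  r = %.4f, p = %.4g, k = %d contrast pairs\n",
              x$estimate, x$p.value, x$n))
  invisible(x)
}

#' Phylogenetically corrected correlation between two traits
#'
#' Convenience pipeline: computes contrasts for two columns of a species
#' trait table (dropping species missing either trait, with the tree pruned
#' accordingly — pairwise deletion) and correlates them.
#'
#' @param traits Data frame with a `species` column.
#' @param tree A `"phylo"` object covering the species.
#' @param x,y Trait column names.
#' @param method Passed to [pic_correlation()].
#' @param log10_branches Apply [log10_branch_transform()] to the (pruned)
#'   tree before computing contrasts.
#' @return A `"recombevol_cor"` object; the contrast pairs are attached as
#'   attribute `"contrasts"` (a tibble with `node`, `contrast_x`,
#'   `contrast_y`).
#' @export
correlate_traits <- function(traits, tree, x, y,
                             method = "pearson_origin",
                             log10_branches = FALSE) {
  keep <- traits$species[!is.na(traits[[x]]) & !is.na(traits[[y]])]
  keep <- intersect(tree$tip.label, keep)
  if (length(keep) < 3) abort("fewer than 3 species with both traits")
  tr <- if (length(keep) < ape::Ntip(tree)) {
    ape::drop.tip(tree, setdiff(tree$tip.label, keep))
  } else {
    tree
  }
  if (log10_branches) tr <- log10_branch_transform(tr)
  rows <- match(keep, traits$species)
  xv <- setNames(traits[[x]][rows], keep)
  yv <- setNames(traits[[y]][rows], keep)
  cs_x <- pic_contrasts(tr, xv)
  cs_y <- pic_contrasts(tr, yv)
  out <- pic_correlation(cs_x, cs_y, method = method)
  attr(out, "contrasts") <- tibble(
    node = cs_x$node, contrast_x = cs_x$contrast, contrast_y = cs_y$contrast
  )
  attr(out, "traits") <- c(x = x, y = y)
  out
}

#' Cook's distance for a through-origin regression
#'
#' Influence of each contrast pair on the through-origin least-squares fit
#' of `y` on `x` (one parameter):
#' \eqn{D_i = e_i^2 h_i / (s^2 (1 - h_i)^2)} with leverage
#' \eqn{h_i = x_i^2/\sum x^2} and \eqn{s^2 = \sum e^2/(k-1)}. Used to flag
#' contrasts (sister-species comparisons) that dominate a reported
#' correlation.
#'
#' @param cs_x,cs_y Contrast tibbles or numeric vectors.
#' @return A tibble with `index`, `leverage`, `residual`, `cooks_d`.
#' @export
cooks_distance_origin <- function(cs_x, cs_y) {
  x <- if (is.data.frame(cs_x)) cs_x$contrast else as.numeric(cs_x)
  y <- if (is.data.frame(cs_y)) cs_y$contrast else as.numeric(cs_y)
  k <- length(x)
  if (k < 3) abort("need at least 3 points")
  sxx <- sum(x^2)
  if (sxx == 0) abort("all x are zero: slope undefined")
  beta <- sum(x * y) / sxx
  e <- y - beta * x
  h <- x^2 / sxx
  s2 <- sum(e^2) / (k - 1)
  d <- if (s2 == 0) rep(0, k) else e^2 * h / (s2 * (1 - h)^2)
  tibble(index = seq_len(k), leverage = h, residual = e, cooks_d = d)
}

#' Assign values to empirical quartile bins
#'
#' Bins a numeric trait into quartiles Q1 (lowest) to Q4 (highest) using
#' type-7 quantile breaks. Values equal to an internal break fall in the
#' lower bin. If all values are equal the quartiles collapse: a warning is
#' issued and every value is assigned Q1.
#'
#' @param values Numeric vector (length >= 4 after removing `NA`).
#' @param labels Optional element names for the result.
#' @return Factor of labels `Q1`-`Q4` (NA where `values` is NA).
#' @export
quartile_bins <- function(values, labels = names(values)) {
  ok <- !is.na(values)
  if (sum(ok) < 4) abort("need at least 4 non-missing values")
  br <- quantile(values[ok], probs = seq(0, 1, 0.25), type = 7, names = FALSE)
  if (length(unique(br)) < 5) {
    if (diff(range(values[ok])) == 0) {
      warn("all values equal: quartiles collapse, assigning Q1 to all")
      out <- factor(ifelse(ok, "Q1", NA), levels = paste0("Q", 1:4))
      names(out) <- labels
      return(out)
    }
    br <- unique(br)
  }
  bins <- cut(values, breaks = br, include.lowest = TRUE, right = TRUE,
              labels = paste0("Q", seq_len(length(br) - 1)))
  levels(bins) <- paste0("Q", seq_along(levels(bins)))
  names(bins) <- labels
  bins
}
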