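#' Does a gene family span the root of the species tree?
#'
#' A family "spans the root" when it has at least one gene on each side of
#' the root bipartition — evidence the family existed in the common
#' ancestor, so per-species counts (including zeros) are comparable.
#'
#' @param counts Named integer vector of gene counts per species for one
#'   family, or a one-row slice of a family table in long form.
#' @param root_split A list of two non-overlapping character vectors
#'   partitioning the species set (e.g. from `split_at_root()`).
#' @return `TRUE`/`FALSE`.
#' @export
family_spans_root <- function(counts, root_split) {
  unknown <- setdiff(names(counts), c(root_split[[1]], root_split[[2]]))
  if (length(unknown) > 0) {
    abort(paste0("species not in the root split: ",
                 paste(unknown, collapse = ", ")))
  }
  side1 <- sum(counts[names(counts) %in% root_split[[1]]]) > 0
  side2 <- sum(counts[names(counts) %in% root_split[[2]]]) > 0
  side1 && side2
}

#' Root bipartition of a rooted tree
#'
#' @param tree A rooted `"phylo"` object.
#' @return List of two character vectors: the tip sets of the root's two
#'   daughter clades.
#' @export
split_at_root <- function(tree) {
  validate_phylo(tree)
  root <- ape::Ntip(tree) + 1
  children <- tree$edge[tree$edge[, 1] == root, 2]
  if (length(children) != 2) abort("root is not bifurcating")
  tips_of <- function(node) {
    if (node <= ape::Ntip(tree)) return(tree$tip.label[node])
    tree$tip.label[ape::prop.part(tree)[[node - ape::Ntip(tree)]]]
  }
  lapply(children, tips_of)
}

#' Average gene family size per species
#'
#' For each species, the mean number of genes per root-spanning family,
#' counting 0 for families in which the species has no gene. Counting
#' zeros is what allows averages below 1 (species absent from many
#' conserved families). Optionally, the largest families (by total gene
#' count across species) are trimmed before averaging, keeping the smallest
#' `trim_fraction` of families — a robustness check against a few massive
#' family expansions driving the trait.
#'
#' @param families Tibble in long form: columns `family`, `species`,
#'   `count` (absent combinations are treated as zero).
#' @param root_split List of two species vectors (see [split_at_root()]);
#'   `NULL` skips the root-span filter.
#' @param trim_fraction Keep only the smallest fraction of families by
#'   total size (e.g. `0.75`); `NULL` keeps all.
#' @return Tibble with `species`, `avg_family_size`, `n_families`.
#' @export
average_gene_family_size <- function(families, root_split = NULL,
                                     trim_fraction = NULL) {
  need <- c("family", "species", "count")
  if (!all(need %in% names(families))) {
    abort("`families` needs columns family, species, count")
  }
  if (any(families$count < 0)) abort("negative gene count")
  species_all <- if (is.null(root_split)) {
    sort(unique(families$species))
  } else {
    c(root_split[[1]], root_split[[2]])
  }

  wide <- families %>%
    filter(.data$species %in% species_all) %>%
    group_by(.data$family, .data$species) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "species", values_from = "count",
                       values_fill = 0)
  for (sp in setdiff(species_all, names(wide))) wide[[sp]] <- 0

  if (!is.null(root_split)) {
    spans <- vapply(seq_len(nrow(wide)), function(i) {
      cnt <- unlist(wide[i, species_all])
      family_spans_root(setNames(as.numeric(cnt), species_all), root_split)
    }, logical(1))
    wide <- wide[spans, ]
  }
  if (!is.null(trim_fraction)) {
    tot <- rowSums(wide[, species_all])
    cutoff <- quantile(tot, probs = trim_fraction, type = 7)
    wide <- wide[tot <= cutoff, ]
  }
  if (nrow(wide) == 0) abort("no families left after filtering")

  tibble(
    species = species_all,
    avg_family_size = unname(vapply(species_all,
                                    function(sp) mean(wide[[sp]]),
                                    numeric(1))),
    n_families = nrow(wide)
  )
}
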