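#' Run the full comparative study
#'
#' Wires the modules into the end-to-end workflow: assemble (or accept) a
#' species trait table, test each trait for phylogenetic signal, compute
#' the pairwise phylogenetically corrected correlation matrix with power
#' annotations, and screen the per-gene coevolution table. Results are
#' returned as tibbles and, when `out_dir` is given, written as TSV plus a
#' JSON manifest recording seeds and flags so a rerun is reproducible.
#'
#' Missing data are handled by pairwise deletion: each correlation uses
#' the species with both traits present, with the tree pruned accordingly.
#'
#' @param tree A `"phylo"` object (or path to a newick file).
#' @param traits Species trait table (data frame with `species` column) or
#'   path to a TSV.
#' @param trait_columns Columns to analyse (default: all numeric).
#' @param coevol Optional per-gene coevolution table (or TSV path) for
#'   [coevol_screen()].
#' @param reps Permutations for the signal tests (default 999).
#' @param seed Integer seed for the permutation tests.
#' @param log10_branches Apply the base-10 branch-length transform before
#'   contrasts (requires all branches > 1).
#' @param method Correlation method for contrasts.
#' @param target_fraction Significant fraction for the screen.
#' @param out_dir Optional output directory.
#' @return A list with `traits`, `signal` (K table), `correlations`
#'   (pairwise tibble with r, p, n, power), and `screen` (or `NULL`).
#' @export
run_study <- function(tree, traits, trait_columns = NULL, coevol = NULL,
                      reps = 999, seed = 1, log10_branches = FALSE,
                      method = "pearson_origin", target_fraction = 0.05,
                      out_dir = NULL) {
  if (is.character(tree)) tree <- read_newick(tree)
  if (is.character(traits)) {
    if (!file.exists(traits)) abort(paste0("trait file not found: ", traits))
    traits <- readr::read_tsv(traits, show_col_types = FALSE)
  }
  if (is.character(coevol)) {
    if (!file.exists(coevol)) abort(paste0("coevol file not found: ", coevol))
    coevol <- readr::read_tsv(coevol, show_col_types = FALSE)
  }
  if (is.null(trait_columns)) {
    trait_columns <- names(traits)[vapply(traits, is.numeric, logical(1))]
  }

  signal <- phylo_signal_table(traits, tree, trait_columns,
                               reps = reps, seed = seed)

  pairs <- utils::combn(trait_columns, 2, simplify = FALSE)
  correlations <- purrr::map_dfr(pairs, function(pr) {
    res <- tryCatch(
      correlate_traits(traits, tree, pr[1], pr[2], method = method,
                       log10_branches = log10_branches),
      error = function(e) NULL
    )
    if (is.null(res)) {
      return(tibble(x = pr[1], y = pr[2], r = NA_real_, p.value = NA_real_,
                    n_species = NA_integer_, power = NA_real_))
    }
    tibble(
      x = pr[1], y = pr[2], r = res$estimate, p.value = res$p.value,
      n_species = res$n + 1L,
      power = correlation_power(min(abs(res$estimate), 1 - 1e-12),
                                res$n + 1)$power
    )
  })

  screen <- if (!is.null(coevol)) {
    coevol_screen(coevol, target_fraction = target_fraction)
  }

  out <- list(traits = as_tibble(traits), signal = signal,
              correlations = correlations, screen = screen)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(out$traits, file.path(out_dir, "trait_table.tsv"))
    readr::write_tsv(signal, file.path(out_dir, "phylo_signal.tsv"))
    readr::write_tsv(correlations, file.path(out_dir, "pic_correlations.tsv"))
    if (!is.null(screen)) {
      readr::write_tsv(glance(screen), file.path(out_dir, "screen_summary.tsv"))
      readr::write_tsv(screen$records, file.path(out_dir, "screen_genes.tsv"))
    }
    manifest <- list(
      package = "recombevol",
      version = as.character(utils::packageVersion("recombevol")),
      seed = seed, reps = reps, method = method,
      log10_branches = log10_branches,
      target_fraction = target_fraction,
      trait_columns = trait_columns,
      n_species = ape::Ntip(tree)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
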