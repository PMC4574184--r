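#' Read and validate a phylogeny from newick
#'
#' Reads a single rooted tree from a newick string or file and validates it
#' for comparative use: unique, non-empty tip labels; branch lengths present
#' on every non-root edge; branch lengths non-negative. Quoted labels and
#' square-bracket comments are tolerated by the parser; internal node labels
#' are preserved. The tree is returned as an [ape::read.tree()] `"phylo"`
#' object, the standard container for downstream work.
#'
#' @param x A newick string (must end in `;`) or a path to a newick file
#'   containing a single tree.
#' @return A validated `"phylo"` object.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  tr <- if (grepl(";", x, fixed = TRUE)) {
    ape::read.tree(text = x)
  } else {
    if (!file.exists(x)) abort(paste0("tree file not found: ", x))
    ape::read.tree(file = x)
  }
  if (is.null(tr)) abort("newick parse error: no tree could be read")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1) abort("expected a single tree, found several")
    tr <- tr[[1]]
  }
  validate_phylo(tr)
}

#' Write a phylogeny to newick
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @param digits Number of significant digits for branch lengths.
#' @return The newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 15) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Validate a phylogeny for comparative analyses
#'
#' @param tree A `"phylo"` object.
#' @param require_binary If `TRUE`, polytomies are an error (contrast and
#'   K computations require a strictly binary tree).
#' @return The tree, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_phylo <- function(tree, require_binary = FALSE) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a \"phylo\" object")
  labs <- tree$tip.label
  if (any(!nzchar(labs))) abort("empty tip label")
  dup <- unique(labs[duplicated(labs)])
  if (length(dup) > 0) {
    abort(paste0("duplicate tip label(s): ", paste(dup, collapse = ", ")))
  }
  if (is.null(tree$edge.length)) abort("branch lengths missing")
  if (length(tree$edge.length) != nrow(tree$edge)) {
    abort("branch length missing on some edge")
  }
  if (anyNA(tree$edge.length)) abort("NA branch length")
  if (any(tree$edge.length < 0)) abort("negative branch length")
  if (require_binary) {
    # explicit child-count check: ape::is.binary treats a 3-tip star as an
    # unrooted binary tree, which would silently corrupt contrasts
    n_children <- tabulate(tree$edge[, 1],
                           nbins = ape::Ntip(tree) + tree$Nnode)
    internal <- (ape::Ntip(tree) + 1):(ape::Ntip(tree) + tree$Nnode)
    if (any(n_children[internal] != 2)) {
      abort("tree has polytomies (or singleton nodes); a strictly binary rooted tree is required")
    }
  }
  invisible(tree)
}

#' Test whether a tree is ultrametric
#'
#' All root-to-tip path lengths must agree within `rel_tol` of the maximum
#' depth. The default tolerance accommodates the numeric precision of
#' divergence-time software output.
#'
#' @param tree A `"phylo"` object.
#' @param rel_tol Relative tolerance (default `1e-6`).
#' @return `TRUE` or `FALSE`.
#' @export
is_ultrametric <- function(tree, rel_tol = 1e-6) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  diff(range(d)) <= rel_tol * max(d)
}

# Root-to-node path lengths for every node (tips first, ape numbering).
node_depths <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(n_node)
  # ape "cladewise" order visits parents before children from the root
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    depth[ord$edge[k, 2]] <- depth[ord$edge[k, 1]] + ord$edge.length[k]
  }
  depth
}

#' Base-10 logarithm transform of branch lengths
#'
#' Replaces every branch length by its base-10 logarithm, leaving the
#' topology untouched. Used to stabilise the contrast variances before
#' computing independent contrasts on deep timetrees. Requires every branch
#' to exceed 1 (in the tree's time unit), since a transformed length \eqn{\le
#' 0} cannot standardise a contrast; branches violating this are reported
#' rather than silently adjusted.
#'
#' @param tree A `"phylo"` object with all branch lengths `> 1`.
#' @return The transformed tree.
#' @examples
#' tr <- read_newick("(A:10,B:100);")
#' log10_branch_transform(tr)$edge.length
#' @export
log10_branch_transform <- function(tree) {
  validate_phylo(tree)
  bad <- which(tree$edge.length <= 1)
  if (length(bad) > 0) {
    abort(paste0(
      "branch length <= 1 on edge(s) ",
      paste(head(bad, 5), collapse = ", "),
      " (parent node ", tree$edge[bad[1], 1], " -> child ",
      tree$edge[bad[1], 2],
      "): log10 transform would give a non-positive length"
    ))
  }
  tree$edge.length <- log10(tree$edge.length)
  tree
}

#' Phylogenetic covariance matrix
#'
#' Returns the matrix `V` of shared root-to-MRCA path lengths between tips
#' (`V[i,i]` is the depth of tip `i`), in tip-label order. This is the
#' Brownian-motion covariance structure used by Blomberg's K and by the
#' generalised-least-squares identities that underpin independent
#' contrasts.
#'
#' @param tree A rooted `"phylo"` object with branch lengths.
#' @return A symmetric numeric matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree) {
  validate_phylo(tree)
  ape::vcv(tree)
}
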