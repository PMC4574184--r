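#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Forward simulation: start from the root split (two lineages at time 0);
#' while `k` lineages exist, wait an exponential time with rate
#' `k * birth_rate`, then split a uniformly chosen lineage; stop at
#' `n_tips`. All tips end at the final event time, so the tree is exactly
#' ultrametric and strictly binary. Expected height is
#' \eqn{\sum_{k=2}^{n-1} 1/(k\lambda)}.
#'
#' @param n_tips Number of tips, `>= 2`.
#' @param birth_rate Speciation rate `lambda > 0` (default 1).
#' @param seed Integer seed; the same seed gives a byte-identical tree.
#' @return An ultrametric `"phylo"` object with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 2) abort("need at least 2 tips")
  if (birth_rate <= 0) abort("birth rate must be positive")
  with_seed(seed, yule_recursive(n_tips, birth_rate))
}

# Forward Yule simulation producing an ape phylo directly.
yule_recursive <- function(n_tips, birth_rate) {
  # Each active lineage: id of its (future) subtree root; we track, per
  # active lineage, the time its pendant branch started. Splits create
  # internal nodes; at the end, tips hang from the last split time.
  max_nodes <- 2 * n_tips - 1
  parent_of <- integer(max_nodes)
  birth_time <- numeric(max_nodes) # time the node's stem began
  is_tip <- logical(max_nodes)
  next_id <- 1L
  new_node <- function(start) {
    id <- next_id
    next_id <<- next_id + 1L
    birth_time[id] <<- start
    id
  }
  root_l <- new_node(0)
  root_r <- new_node(0)
  active <- c(root_l, root_r)
  t_now <- 0
  while (length(active) < n_tips) {
    k <- length(active)
    t_now <- t_now + rexp(1, rate = k * birth_rate)
    i <- sample.int(k, 1)
    a <- new_node(t_now)
    b <- new_node(t_now)
    parent_of[a] <- active[i]
    parent_of[b] <- active[i]
    active <- c(active[-i], a, b)
  }
  t_end <- t_now + rexp(1, rate = length(active) * birth_rate)
  is_tip[active] <- TRUE
  n_internal <- next_id - 1L - n_tips + 1L # internal nodes created + root

  # map to ape numbering: tips 1..n, root n+1, internals follow
  ids <- seq_len(next_id - 1L)
  tip_ids <- ids[is_tip[ids]]
  int_ids <- ids[!is_tip[ids]]
  # internal node end time = birth time of its children; root = 0 children
  ape_num <- integer(next_id - 1L)
  ape_num[tip_ids] <- seq_along(tip_ids)
  ape_num[int_ids] <- n_tips + 1L + seq_along(int_ids)
  root_ape <- n_tips + 1L

  edges <- matrix(0L, nrow = next_id - 2L + 1L, ncol = 2)
  lens <- numeric(nrow(edges))
  end_time <- numeric(next_id - 1L)
  end_time[tip_ids] <- t_end
  # an internal node ends when its children begin
  for (id in ids) {
    p <- parent_of[id]
    if (p > 0) end_time[p] <- birth_time[id]
  }
  row <- 0L
  for (id in ids) {
    p <- parent_of[id]
    to <- ape_num[id]
    from <- if (p == 0) root_ape else ape_num[p]
    if (to == root_ape) next
    row <- row + 1L
    edges[row, ] <- c(from, to)
    lens[row] <- end_time[id] - birth_time[id]
  }
  edges <- edges[seq_len(row), , drop = FALSE]
  lens <- lens[seq_len(row)]
  tr <- list(
    edge = edges,
    edge.length = lens,
    tip.label = paste0("t", seq_len(n_tips)),
    Nnode = n_tips - 1L
  )
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Simulate correlated Brownian-motion traits on a tree
#'
#' Two traits evolve by bivariate Brownian motion from a root value of 0:
#' each branch adds a bivariate normal increment with covariance
#' `Sigma * branch length`. The trait correlation `rho` of the increment
#' process is what phylogenetically corrected correlation methods estimate.
#'
#' @param tree A `"phylo"` object.
#' @param Sigma 2x2 positive-semidefinite rate matrix, or `NULL` to build
#'   one from `rates` and `rho`.
#' @param rates Length-2 vector of per-trait BM variances (default
#'   `c(1, 1)`).
#' @param rho Increment correlation in `[-1, 1]` (default 0).
#' @param seed Integer seed.
#' @param names Trait column names.
#' @return Tibble with `species`, and the two trait columns.
#' @export
simulate_bm_traits <- function(tree, Sigma = NULL, rates = c(1, 1),
                               rho = 0, seed = NULL,
                               names = c("trait1", "trait2")) {
  if (is.null(Sigma)) {
    Sigma <- diag(sqrt(rates)) %*% matrix(c(1, rho, rho, 1), 2) %*%
      diag(sqrt(rates))
  }
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-12)) abort("Sigma is not positive semidefinite")
  # matrix square root (works for PSD, including singular, Sigma)
  es <- eigen(Sigma, symmetric = TRUE)
  A <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), 2) %*% t(es$vectors)

  n <- ape::Ntip(tree)
  n_node <- n + tree$Nnode
  vals <- matrix(0, nrow = n_node, ncol = 2)
  ord <- ape::reorder.phylo(tree, "cladewise")
  with_seed(seed, {
    z <- matrix(rnorm(2 * nrow(ord$edge)), ncol = 2)
    for (k in seq_len(nrow(ord$edge))) {
      child <- ord$edge[k, 2]
      vals[child, ] <- vals[ord$edge[k, 1], ] +
        sqrt(ord$edge.length[k]) * as.numeric(A %*% z[k, ])
    }
  })
  out <- tibble(
    species = tree$tip.label,
    x = vals[seq_len(n), 1],
    y = vals[seq_len(n), 2]
  )
  stats::setNames(out, c("species", names))
}

#' Simulate a finite-marker genetic map
#'
#' Emulates the truncation that marker-density correction repairs: each
#' chromosome has a known true genetic length; `m` markers are placed
#' uniformly at random along it and the observed linkage-group length is
#' the span of the sampled markers, which always underestimates the truth
#' (for `m = 2` the expected span is a third of the true length).
#'
#' @param true_lengths_cM Numeric vector of true per-chromosome lengths.
#' @param markers_per_group Integer (recycled), `>= 2`.
#' @param species,map_id Labels for the output table.
#' @param seed Integer seed.
#' @return A list: `map` (tibble of linkage-group records usable by
#'   [correct_map_length()]) and `true_total_cM`.
#' @export
simulate_genetic_map <- function(true_lengths_cM, markers_per_group = 10,
                                 species = "sim", map_id = "map1",
                                 seed = NULL) {
  if (any(true_lengths_cM <= 0)) abort("true lengths must be positive")
  m <- rep_len(markers_per_group, length(true_lengths_cM))
  if (any(m < 2)) abort("need at least 2 markers per group")
  obs <- with_seed(seed, {
    vapply(seq_along(true_lengths_cM), function(i) {
      pos <- runif(m[i], 0, true_lengths_cM[i])
      diff(range(pos))
    }, numeric(1))
  })
  list(
    map = tibble(
      species = species, map_id = map_id,
      linkage_group = seq_along(true_lengths_cM),
      length_cM = obs, n_markers = m
    ),
    true_total_cM = sum(true_lengths_cM)
  )
}

#' Simulate codon sequences with tunable bias and GC3
#'
#' Draws amino acids uniformly (standard code, no Met/Trp exclusion, no
#' stops) and, within each amino acid, draws synonymous codons from a
#' distribution interpolating between uniform usage (`bias = 0`, ENC near
#' 61) and single-codon usage (`bias = 1`, ENC = 20). Third-position G/C
#' propensity is tilted toward `target_gc3` before the bias mixture is
#' applied.
#'
#' @param n_seqs Number of sequences.
#' @param length_codons Codons per sequence.
#' @param bias Codon-usage bias strength in `[0, 1]`.
#' @param target_gc3 Target third-position G+C propensity in `[0, 1]`
#'   (default 0.5 = no tilt).
#' @param species Species tags (recycled over sequences; ids are
#'   `species|gene<i>`).
#' @param seed Integer seed.
#' @return A codon-alignment tibble (`id`, `species`, `seq`).
#' @export
simulate_codon_sequences <- function(n_seqs, length_codons, bias = 0,
                                     target_gc3 = 0.5, species = "simsp",
                                     seed = NULL) {
  if (bias < 0 || bias > 1) abort("bias must lie in [0, 1]")
  if (target_gc3 < 0 || target_gc3 > 1) abort("target_gc3 must lie in [0, 1]")
  code <- get_code()
  aa_set <- setdiff(unique(code$codon_aa), "*")
  syn <- split(names(code$codon_aa), code$codon_aa)[aa_set]
  sp <- rep_len(species, n_seqs)

  codon_weights <- function(codons) {
    third <- substr(codons, 3, 3)
    w <- ifelse(third %in% c("G", "C"), target_gc3, 1 - target_gc3)
    if (sum(w) == 0) w <- rep(1, length(codons))
    w <- w / sum(w)
    # preferred codon: first in alphabetical order among the heaviest
    pref <- which.max(w)
    (1 - bias) * w + bias * (seq_along(codons) == pref)
  }
  wts <- lapply(syn, codon_weights)

  with_seed(seed, {
    seqs <- vapply(seq_len(n_seqs), function(i) {
      aas <- sample(aa_set, length_codons, replace = TRUE)
      cods <- vapply(aas, function(a) {
        sample(syn[[a]], 1, prob = wts[[a]])
      }, character(1))
      paste(cods, collapse = "")
    }, character(1))
    tibble(
      id = paste0(sp, "|gene", seq_len(n_seqs)),
      species = sp,
      seq = seqs
    )
  })
}

#' Simulate a per-gene coevolution summary table
#'
#' Fabricates the per-gene output of a Bayesian trait--dN/dS coevolution
#' analysis: a mixture of null genes (central posterior probabilities,
#' uniform on (0.05, 0.95)), negative-signal genes (pp ~ Beta(1, beta),
#' concentrated near 0) and positive-signal genes (pp ~ Beta(beta, 1),
#' near 1). Correlation coefficients are signed consistently with pp
#' relative to 0.5; ESS fields fail convergence at a configurable rate.
#'
#' @param n_genes Number of genes.
#' @param fractions Length-3 numeric `(null, negative, positive)` summing
#'   to 1.
#' @param beta Beta-distribution shape for the signal components
#'   (default 50).
#' @param ess_fail_rate Fraction of genes given failing ESS (default 0).
#' @param seed Integer seed.
#' @return Tibble with `gene`, `truth`, `correlation`, `pp`, `min_ess`,
#'   `root_ess`, `tags`.
#' @export
simulate_coevol_table <- function(n_genes, fractions = c(0.95, 0.04, 0.01),
                                  beta = 50, ess_fail_rate = 0,
                                  seed = NULL) {
  if (abs(sum(fractions) - 1) > 1e-9) abort("fractions must sum to 1")
  if (any(fractions < 0)) abort("fractions must be nonnegative")
  with_seed(seed, {
    truth <- sample(c("null", "negative", "positive"), n_genes,
                    replace = TRUE, prob = fractions)
    pp <- numeric(n_genes)
    pp[truth == "null"] <- runif(sum(truth == "null"), 0.05, 0.95)
    pp[truth == "negative"] <- rbeta(sum(truth == "negative"), 1, beta)
    pp[truth == "positive"] <- rbeta(sum(truth == "positive"), beta, 1)
    mag <- rbeta(n_genes, 2, 4)
    correlation <- ifelse(pp > 0.5, mag, -mag)
    correlation[pp == 0.5] <- 0
    fail <- runif(n_genes) < ess_fail_rate
    min_ess <- ifelse(fail, runif(n_genes, 10, 300),
                      runif(n_genes, 301, 2000))
    root_ess <- ifelse(fail, runif(n_genes, 1, 50),
                       runif(n_genes, 51, 500))
    tibble(
      gene = paste0("g", seq_len(n_genes)),
      truth = truth,
      correlation = correlation,
      pp = pp,
      min_ess = min_ess,
      root_ess = root_ess,
      tags = ""
    )
  })
}

#' Simulate a complete synthetic study
#'
#' Generates every input the analysis pipeline consumes: an ultrametric
#' Yule tree, bivariate Brownian-motion traits with a chosen correlation,
#' finite-marker genetic maps per species, codon alignments, and a
#' coevolution summary table. Defaults mirror the scale of a 30-species
#' comparative study.
#'
#' @param n_species Number of species (default 30).
#' @param birth_rate Yule speciation rate (default 0.05 per My, giving
#'   realistic tens-of-My branch lengths).
#' @param rho Brownian correlation between the two traits (default -0.65).
#' @param n_chrom Chromosomes per species (default 10).
#' @param chrom_length_cM True genetic length per chromosome (default 120).
#' @param markers_per_group Markers per linkage group (default 25).
#' @param n_genes Coevolution table size (default 3748).
#' @param coevol_fractions Null/negative/positive gene fractions (default
#'   `c(0.95, 0.04, 0.01)`).
#' @param seed Integer seed.
#' @return A list: `tree`, `traits`, `maps` (linkage-group tibble),
#'   `true_map_lengths`, `alignments`, `coevol`.
#' @export
simulate_study <- function(n_species = 30, birth_rate = 0.05, rho = -0.65,
                           n_chrom = 10, chrom_length_cM = 120,
                           markers_per_group = 25, n_genes = 3748,
                           coevol_fractions = c(0.95, 0.04, 0.01),
                           seed = 1) {
  tree <- simulate_yule_tree(n_species, birth_rate, seed = sub_seed(seed, 1))
  traits <- simulate_bm_traits(
    tree, rho = rho, seed = sub_seed(seed, 2),
    names = c("log_recomb_rate", "log_genome_size")
  )
  maps <- purrr::map(seq_len(n_species), function(i) {
    simulate_genetic_map(
      rep(chrom_length_cM, n_chrom), markers_per_group,
      species = tree$tip.label[i], seed = sub_seed(seed, 100 + i)
    )
  })
  aln <- simulate_codon_sequences(
    n_seqs = n_species, length_codons = 300, bias = 0.3,
    target_gc3 = 0.55, species = tree$tip.label,
    seed = sub_seed(seed, 3)
  )
  coevol <- simulate_coevol_table(
    n_genes, coevol_fractions, seed = sub_seed(seed, 4),
    ess_fail_rate = 0.05
  )
  list(
    tree = tree,
    traits = traits,
    maps = purrr::map_dfr(maps, "map"),
    true_map_lengths = tibble(
      species = tree$tip.label,
      true_total_cM = vapply(maps, function(m) m$true_total_cM, numeric(1))
    ),
    alignments = aln,
    coevol = coevol
  )
}
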