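# Independent oracles used across tests. Each re-derives a quantity by a
# different route than the package implementation.

# Brute-force phylogenetic covariance: sum per-edge indicator outer products.
vcv_brute_force <- function(tree) {
  n <- ape::Ntip(tree)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2]
    desc <- if (child <= n) {
      tree$tip.label[child]
    } else {
      ape::extract.clade(tree, child)$tip.label
    }
    V[desc, desc] <- V[desc, desc] + tree$edge.length[k]
  }
  V
}

# GLS slope of y on x after centering both by their phylogenetic means.
gls_slope <- function(tree, x, y) {
  V <- recombevol::phylo_vcv(tree)
  Vi <- solve(V)
  one <- rep(1, nrow(V))
  xo <- x[rownames(V)]
  yo <- y[rownames(V)]
  d1 <- as.numeric(one %*% Vi %*% one)
  xc <- xo - as.numeric(one %*% Vi %*% xo) / d1
  yc <- yo - as.numeric(one %*% Vi %*% yo) / d1
  as.numeric(xc %*% Vi %*% yc) / as.numeric(xc %*% Vi %*% xc)
}

# Wright's effective-number-of-codons statistic, recomputed from scratch
# with an explicit code table (independent of the package's Biostrings
# bookkeeping).
enc_oracle <- function(seq) {
  aa_of <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
    CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
    TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
    GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
    AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
    CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G"
  )
  fam_size <- table(aa_of[aa_of != "*"])
  cods <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  cods <- cods[cods %in% names(aa_of)]
  aas <- aa_of[cods]
  keep <- !(aas %in% c("*", "M", "W"))
  cods <- cods[keep]
  aas <- aas[keep]
  f_by_class <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (a in unique(aas)) {
    cnt <- table(cods[aas == a])
    na <- sum(cnt)
    if (na < 2) next
    p <- cnt / na
    f <- (na * sum(p^2) - 1) / (na - 1)
    s <- as.character(fam_size[[a]])
    f_by_class[[s]] <- c(f_by_class[[s]], f)
  }
  means <- vapply(f_by_class, function(v) {
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  if (anyNA(means[c("2", "4", "6")])) return(NA_real_)
  if (is.na(means[["3"]])) means[["3"]] <- mean(means[c("2", "4")])
  nc <- 2 + 9 / means[["2"]] + 1 / means[["3"]] + 5 / means[["4"]] +
    3 / means[["6"]]
  min(nc, 61)
}

# Two-sided Fisher exact p by complete enumeration over tables with the
# observed margins (probability-mass rule, with the same relative-error
# guard R uses for ties).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b      # row 1 total
  n2 <- c + d     # row 2 total
  k <- a + c      # column 1 total
  lo <- max(0, k - n2)
  hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k))
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A sequence using every synonymous codon of every degenerate amino acid
# equally often (`copies` of each); the analytic maximum-diversity input.
balanced_codon_seq <- function(copies = 12) {
  gc <- Biostrings::GENETIC_CODE
  use <- names(gc)[!(gc %in% c("*", "M", "W"))]
  paste(rep(use, each = copies), collapse = "")
}

# One codon per amino acid, repeated: the maximal-bias input (ENC = 20).
single_codon_seq <- function(copies = 12) {
  gc <- Biostrings::GENETIC_CODE
  aa <- setdiff(unique(gc), "*")
  first <- vapply(aa, function(a) names(gc)[gc == a][1], character(1))
  paste(rep(first, each = copies), collapse = "")
}
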