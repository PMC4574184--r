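# Standard genetic code bookkeeping, built once at load from the Biostrings
# code table. Synonymous-family sizes (excluding Met, Trp and stops):
# 2-fold: Phe Tyr Cys His Gln Asn Lys Asp Glu; 3-fold: Ile;
# 4-fold: Val Pro Thr Ala Gly; 6-fold: Leu Ser Arg.
codon_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  fam <- table(gc[gc != "*"])
  list(
    codon_aa = gc,
    family_size = setNames(as.integer(fam), names(fam)),
    stops = names(gc)[gc == "*"]
  )
}
.code <- NULL
get_code <- function() {
  if (is.null(.code)) {
    utils::assignInMyNamespace(".code", codon_code())
  }
  .code
}

split_codons <- function(seq) {
  seq <- toupper(gsub("\\s", "", seq))
  if (nchar(seq) %% 3 != 0) {
    abort(paste0("sequence length ", nchar(seq), " not divisible by 3"))
  }
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Read an in-frame codon alignment from FASTA
#'
#' Reads nucleotide FASTA (via Biostrings) and returns a tibble of
#' records. Sequence ids of the form `species|gene` have the species tag
#' extracted into its own column.
#'
#' @param path FASTA file path.
#' @return Tibble with `id`, `species` (NA when no tag), `seq`.
#' @export
read_codon_alignment <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- names(ss)
  tibble(
    id = ids,
    species = ifelse(grepl("|", ids, fixed = TRUE),
                     sub("\\|.*$", "", ids), NA_character_),
    seq = unname(as.character(ss))
  )
}

#' Validate an in-frame codon alignment
#'
#' Checks that all sequences have equal length divisible by 3, that gaps
#' occur only in whole-codon units, and that no sequence contains an
#' internal stop codon (standard code). Codons containing `N` or gaps are
#' permitted (they are skipped by the composition statistics) but counted in
#' the report.
#'
#' @param aln Tibble from [read_codon_alignment()] (columns `id`, `seq`),
#'   or a named character vector of sequences.
#' @return The alignment tibble, with attribute `"flagged"` counting
#'   ambiguous/gap codons per record. Errors describe the first offending
#'   record and position.
#' @export
validate_codon_alignment <- function(aln) {
  if (!is.data.frame(aln)) {
    aln <- tibble(id = names(aln), species = NA_character_,
                  seq = unname(aln))
  }
  lens <- nchar(aln$seq)
  if (length(unique(lens)) > 1) abort("records differ in aligned length")
  code <- get_code()
  flagged <- integer(nrow(aln))
  for (i in seq_len(nrow(aln))) {
    cods <- split_codons(aln$seq[i])
    partial_gap <- grepl("-", cods) & cods != "---"
    if (any(partial_gap)) {
      abort(paste0("record ", aln$id[i], ": gap not in whole-codon unit at codon ",
                   which(partial_gap)[1]))
    }
    clean <- !grepl("[^ACGT]", cods)
    is_stop <- clean & cods %in% code$stops
    # a terminal stop is tolerated; internal stops are not
    internal_stop <- is_stop & seq_along(cods) < length(cods)
    if (any(internal_stop)) {
      abort(paste0("record ", aln$id[i], ": internal stop codon at codon ",
                   which(internal_stop)[1]))
    }
    flagged[i] <- sum(!clean)
  }
  attr(aln, "flagged") <- flagged
  aln
}

#' Effective number of codons (Wright's ENC)
#'
#' Wright's codon-usage-bias statistic, ranging from 20 (exactly one codon
#' used per amino acid) to 61 (uniform synonymous usage). For each amino
#' acid with \eqn{n_a \ge 2} counted codons, the codon homozygosity is
#' estimated as \eqn{\hat F_a = (n_a \sum_i p_i^2 - 1)/(n_a - 1)}; class
#' means \eqn{\bar F_s} are taken over amino acids of synonymous-family
#' size \eqn{s \in \{2,3,4,6\}}, and
#' \deqn{N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6,}
#' capped at 61. Edge rules: amino acids observed fewer than twice are
#' excluded from their class mean; if Ile (the only 3-fold class member) is
#' unavailable, \eqn{\bar F_3} is interpolated as the mean of \eqn{\bar F_2}
#' and \eqn{\bar F_4}; if any of classes 2, 4 or 6 is entirely unavailable
#' the statistic is `NA`. Codons with `N` or gaps, stop codons, Met and Trp
#' never contribute.
#'
#' @param seq A coding nucleotide sequence (string, length divisible by 3).
#' @return ENC value in `[20, 61]`, or `NA` if undefined.
#' @examples
#' enc(strrep("GCTGCC", 30)) # heavy bias within Ala
#' @export
enc <- function(seq) {
  code <- get_code()
  cods <- split_codons(seq)
  cods <- cods[!grepl("[^ACGT]", cods)]
  aa <- code$codon_aa[cods]
  keep <- !is.na(aa) & aa != "*" & aa != "M" & aa != "W"
  cods <- cods[keep]
  aa <- aa[keep]
  if (length(cods) == 0) abort("no usable codons")

  fhat <- function(codons) {
    n <- length(codons)
    if (n < 2) return(NA_real_)
    p <- as.numeric(table(codons)) / n
    (n * sum(p^2) - 1) / (n - 1)
  }
  per_aa <- tapply(cods, aa, fhat)
  fam <- code$family_size[names(per_aa)]

  class_mean <- function(s) {
    v <- per_aa[fam == s & !is.na(per_aa)]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  f2 <- class_mean(2)
  f3 <- class_mean(3)
  f4 <- class_mean(4)
  f6 <- class_mean(6)
  if (anyNA(c(f2, f4, f6))) return(NA_real_)
  if (is.na(f3)) f3 <- mean(c(f2, f4)) # Wright's interpolation for Ile
  if (any(c(f2, f3, f4, f6) <= 0)) return(NA_real_)
  nc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  min(nc, 61)
}

# First two bases of codons whose third position is fourfold degenerate.
fourfold_prefixes <- function(strict = FALSE) {
  pure <- c("GC", "GG", "CC", "AC", "GT")        # Ala Gly Pro Thr Val
  if (strict) pure else c(pure, "CT", "CG", "TC") # + Leu Arg Ser subgroups
}

#' GC content at fourfold-degenerate third codon positions (GC3s)
#'
#' Fraction of G or C at the third position among codons whose third
#' position is fourfold degenerate — a near-neutral marker of compositional
#' bias (e.g. from GC-biased gene conversion). By default the fourfold
#' subgroups of the sixfold amino acids (Leu CTN, Arg CGN, Ser TCN) are
#' included, since fourfold degeneracy is a property of the site;
#' `strict_fourfold_aa = TRUE` restricts to the five purely fourfold amino
#' acids (Ala, Gly, Pro, Thr, Val). Codons containing `N` or gaps are
#' excluded.
#'
#' @param seq A coding nucleotide sequence.
#' @param strict_fourfold_aa Use only the purely fourfold amino acids.
#' @return GC3s in `[0, 1]`; error if no eligible codon.
#' @examples
#' gc3s("GCTGCCGCAGCG") # 0.5
#' @export
gc3s <- function(seq, strict_fourfold_aa = FALSE) {
  cods <- split_codons(seq)
  cods <- cods[!grepl("[^ACGT]", cods)]
  pref <- substr(cods, 1, 2)
  eligible <- pref %in% fourfold_prefixes(strict_fourfold_aa)
  if (!any(eligible)) abort("no fourfold-degenerate codons in sequence")
  third <- substr(cods[eligible], 3, 3)
  mean(third %in% c("G", "C"))
}

#' Per-sequence and per-species codon composition
#'
#' Computes ENC and GC3s for every record of one or more codon alignments
#' and averages them (unweighted) within species.
#'
#' @param alignments A tibble (or list of tibbles) with columns `id`,
#'   `species`, `seq` (see [read_codon_alignment()]).
#' @param strict_fourfold_aa Passed to [gc3s()].
#' @return A list with `sequences` (per-record tibble: `id`, `species`,
#'   `enc`, `gc3s`) and `species` (per-species means `mean_enc`,
#'   `mean_gc3s`, `n_sequences`).
#' @export
per_species_composition <- function(alignments, strict_fourfold_aa = FALSE) {
  if (is.data.frame(alignments)) alignments <- list(alignments)
  seq_tbl <- purrr::map_dfr(alignments, function(aln) {
    tibble(
      id = aln$id,
      species = aln$species,
      enc = vapply(aln$seq, function(s) {
        tryCatch(enc(s), error = function(e) NA_real_)
      }, numeric(1), USE.NAMES = FALSE),
      gc3s = vapply(aln$seq, function(s) {
        tryCatch(gc3s(s, strict_fourfold_aa), error = function(e) NA_real_)
      }, numeric(1), USE.NAMES = FALSE)
    )
  })
  sp_tbl <- seq_tbl %>%
    filter(!is.na(.data$species)) %>%
    group_by(.data$species) %>%
    summarise(
      mean_enc = mean(.data$enc, na.rm = TRUE),
      mean_gc3s = mean(.data$gc3s, na.rm = TRUE),
      n_sequences = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(across(c("mean_enc", "mean_gc3s"), ~ ifelse(is.nan(.x), NA, .x)))
  list(sequences = seq_tbl, species = sp_tbl)
}
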