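#' Read genetic maps from a TSV file
#'
#' Expected columns: `species`, `map_id`, `linkage_group`, `length_cM`,
#' `n_markers`. One row per linkage group. `"NA"` marks missing values.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble of linkage-group records.
#' @export
read_genetic_maps <- function(path) {
  maps <- readr::read_tsv(path, show_col_types = FALSE)
  validate_genetic_maps(maps)
}

#' Validate genetic-map records
#'
#' Checks the per-linkage-group table: observed lengths non-negative, marker
#' counts at least 2, and — when a species' haploid chromosome number is
#' supplied — that each map has exactly that many linkage groups. Maps whose
#' linkage-group count disagrees with the chromosome number are rejected,
#' since extra or fused groups signal an unsaturated or mis-assembled map.
#'
#' @param maps Tibble with columns `species`, `map_id`, `linkage_group`,
#'   `length_cM`, `n_markers`.
#' @param n_chrom Optional named vector (or tibble with `species`,
#'   `n_chrom`) of haploid chromosome numbers used to screen maps.
#' @return The validated tibble (maps failing the chromosome-number screen
#'   removed, with a warning naming them).
#' @export
validate_genetic_maps <- function(maps, n_chrom = NULL) {
  need <- c("species", "map_id", "linkage_group", "length_cM", "n_markers")
  miss <- setdiff(need, names(maps))
  if (length(miss) > 0) {
    abort(paste0("genetic map table lacks column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(maps$length_cM < 0, na.rm = TRUE)) abort("negative map length")
  if (any(maps$n_markers < 2, na.rm = TRUE)) {
    abort("linkage group with fewer than 2 markers")
  }
  if (!is.null(n_chrom)) {
    if (is.data.frame(n_chrom)) {
      n_chrom <- setNames(n_chrom$n_chrom, n_chrom$species)
    }
    counts <- maps %>%
      group_by(.data$species, .data$map_id) %>%
      summarise(n_lg = dplyr::n(), .groups = "drop") %>%
      mutate(expected = unname(n_chrom[.data$species]))
    bad <- counts %>%
      filter(!is.na(.data$expected), .data$n_lg != .data$expected)
    if (nrow(bad) > 0) {
      warn(paste0(
        "dropping map(s) whose linkage-group count differs from the ",
        "haploid chromosome number: ",
        paste(paste0(bad$species, "/", bad$map_id), collapse = ", ")
      ))
      maps <- maps %>%
        dplyr::anti_join(bad %>% select("species", "map_id"),
                         by = c("species", "map_id"))
    }
  }
  as_tibble(maps)
}

#' Marker-density-corrected map length (Chakravarti's method 4)
#'
#' A linkage group mapped with finitely many markers underestimates its true
#' genetic length because recombination beyond the terminal markers is
#' unobserved. Method 4 inflates each group's observed length by
#' \eqn{(m+1)/(m-1)}, where `m` is the group's marker count, and the
#' corrected map length is the sum over groups. The correction vanishes as
#' maps become saturated (`m` large) and always yields a length at least the
#' observed total.
#'
#' @param maps Tibble of linkage-group records (see [read_genetic_maps()]).
#' @return Tibble with one row per `species` x `map_id`:
#'   `observed_length_cM`, `corrected_length_cM`, `n_linkage_groups`.
#' @examples
#' m <- tibble::tibble(species = "sp", map_id = "m1", linkage_group = 1,
#'                     length_cM = 100, n_markers = 11)
#' correct_map_length(m)$corrected_length_cM # 120
#' @export
correct_map_length <- function(maps) {
  if (nrow(maps) == 0) abort("empty map table")
  if (any(maps$n_markers < 2)) abort("marker count < 2: correction undefined")
  maps %>%
    group_by(.data$species, .data$map_id) %>%
    summarise(
      observed_length_cM = sum(.data$length_cM),
      corrected_length_cM = sum(
        .data$length_cM * (.data$n_markers + 1) / (.data$n_markers - 1)
      ),
      n_linkage_groups = dplyr::n(),
      .groups = "drop"
    )
}

#' Average corrected map length per species
#'
#' Multiple published maps of the same species are each corrected for marker
#' density and then averaged (correct first, then mean: the correction
#' factor is map-specific through its marker counts).
#'
#' @param maps Tibble of linkage-group records, possibly several `map_id`s
#'   per species.
#' @return Tibble with `species`, `L_corr_cM` (mean corrected length),
#'   `n_maps`.
#' @export
average_corrected_length <- function(maps) {
  correct_map_length(maps) %>%
    group_by(.data$species) %>%
    summarise(
      L_corr_cM = mean(.data$corrected_length_cM),
      n_maps = dplyr::n(),
      .groups = "drop"
    )
}

#' Global recombination rate (cM/Mb)
#'
#' Corrected map length divided by genome size, where genome size is the
#' total (mapped plus unmapped) assembly size in Mb.
#'
#' @param L_corr Corrected map length in cM (vectorised).
#' @param G Genome size in Mb, `> 0`.
#' @return Rate in cM/Mb.
#' @export
global_recomb_rate <- function(L_corr, G) {
  stopifnot(all(L_corr >= 0 | is.na(L_corr)))
  if (any(G <= 0, na.rm = TRUE)) abort("genome size must be positive")
  L_corr / G
}

#' Global recombination rate per C-value (cM/pg)
#'
#' Uses the haploid DNA content in picograms as an assembly-independent
#' genome-size measure, sidestepping under-assembly of repetitive DNA.
#'
#' @param L_corr Corrected map length in cM.
#' @param c_value C-value in pg, `> 0`.
#' @return Rate in cM/pg.
#' @export
cvalue_recomb_rate <- function(L_corr, c_value) {
  if (any(c_value <= 0, na.rm = TRUE)) abort("C-value must be positive")
  L_corr / c_value
}

#' Euchromatin-corrected recombination rate (cM/Mb)
#'
#' Crossovers are largely confined to euchromatin. Assuming 95% of the
#' genetic map lies in the euchromatic fraction of the genome, the corrected
#' rate relates euchromatic map length to euchromatic physical size:
#' \deqn{\rho_e = 0.95\, L_{corr} / (G (1 - h))}
#' with `h` the heterochromatin fraction. Consequently
#' \eqn{\rho_e/\rho = 0.95/(1-h)}.
#'
#' @param L_corr Corrected map length in cM.
#' @param G Genome size in Mb.
#' @param h Heterochromatin fraction in `[0, 1)`.
#' @param map_euchromatic_fraction Fraction of the genetic map assumed
#'   euchromatic (default 0.95).
#' @return Rate in cM/Mb.
#' @export
euchromatin_recomb_rate <- function(L_corr, G, h,
                                    map_euchromatic_fraction = 0.95) {
  if (any(h < 0 | h >= 1, na.rm = TRUE)) {
    abort("heterochromatin fraction must lie in [0, 1)")
  }
  if (any(G <= 0, na.rm = TRUE)) abort("genome size must be positive")
  (map_euchromatic_fraction * L_corr) / (G * (1 - h))
}

#' Genome size without LTR retrotransposons (Mb)
#'
#' @param G Genome size in Mb.
#' @param p_ltr Proportion of the genome that is LTR retrotransposon,
#'   in `[0, 1]`.
#' @return Size in Mb.
#' @export
genome_size_without_ltr <- function(G, p_ltr) {
  if (any(p_ltr < 0 | p_ltr > 1, na.rm = TRUE)) {
    abort("LTR proportion must lie in [0, 1]")
  }
  G * (1 - p_ltr)
}

#' Gene density (genes/Mb)
#'
#' @param n_genes Predicted gene count.
#' @param G Genome size in Mb.
#' @return Genes per Mb.
#' @export
gene_density <- function(n_genes, G) {
  if (any(G <= 0, na.rm = TRUE)) abort("genome size must be positive")
  n_genes / G
}

#' Genome compactness (Mb per chromosome)
#'
#' Genome size over the haploid chromosome number; a proxy for chromosome
#' (arm) length, which sets a floor on per-chromosome crossover counts.
#'
#' @param G Genome size in Mb.
#' @param n_chrom Haploid chromosome number, `>= 1`.
#' @return Mb per chromosome.
#' @export
genome_compactness <- function(G, n_chrom) {
  if (any(n_chrom < 1, na.rm = TRUE)) abort("n_chrom must be >= 1")
  G / n_chrom
}

#' Assemble the species trait table
#'
#' Joins genome profiles with averaged, marker-density-corrected map lengths
#' and derives the architecture traits: global rate (cM/Mb), per-C-value
#' rate (cM/pg, when C-values are given), euchromatin-corrected rate
#' (missing when the heterochromatin fraction is missing), genome size
#' without LTR retrotransposons, gene density and compactness. Missing
#' inputs propagate to missing outputs; nothing is imputed.
#'
#' @param profiles Tibble with one row per species: `species`,
#'   `genome_size_Mb`, and optionally `heterochromatin_fraction`,
#'   `ltr_proportion`, `copia_proportion`, `gypsy_proportion`,
#'   `predicted_gene_count`, `n_chrom`, `c_value_pg`.
#' @param maps Tibble of linkage-group records covering the same species.
#' @return A tibble, one row per species, with derived trait columns and a
#'   `"units"` attribute naming each column's unit.
#' @export
build_trait_table <- function(profiles, maps) {
  if (!all(c("species", "genome_size_Mb") %in% names(profiles))) {
    abort("profiles need columns `species` and `genome_size_Mb`")
  }
  lens <- average_corrected_length(maps)
  missing_prof <- setdiff(lens$species, profiles$species)
  if (length(missing_prof) > 0) {
    abort(paste0("species with maps but no profile: ",
                 paste(missing_prof, collapse = ", ")))
  }
  optional <- c("ltr_proportion", "heterochromatin_fraction",
                "predicted_gene_count", "n_chrom", "c_value_pg")
  for (col in setdiff(optional, names(profiles))) {
    profiles[[col]] <- NA_real_
  }
  out <- profiles %>%
    left_join(lens, by = "species") %>%
    mutate(
      recomb_rate_cM_Mb =
        global_recomb_rate(.data$L_corr_cM, .data$genome_size_Mb),
      recomb_rate_cM_pg = ifelse(
        is.na(.data$c_value_pg), NA_real_,
        .data$L_corr_cM / .data$c_value_pg
      ),
      euchromatin_rate_cM_Mb = ifelse(
        is.na(.data$heterochromatin_fraction), NA_real_,
        0.95 * .data$L_corr_cM /
          (.data$genome_size_Mb * (1 - .data$heterochromatin_fraction))
      ),
      genome_size_no_ltr_Mb = ifelse(
        is.na(.data$ltr_proportion), NA_real_,
        .data$genome_size_Mb * (1 - .data$ltr_proportion)
      ),
      gene_density_per_Mb = ifelse(
        is.na(.data$predicted_gene_count), NA_real_,
        .data$predicted_gene_count / .data$genome_size_Mb
      ),
      compactness_Mb_per_chrom = ifelse(
        is.na(.data$n_chrom), NA_real_,
        .data$genome_size_Mb / .data$n_chrom
      )
    ) %>%
    as_tibble()
  attr(out, "units") <- c(
    L_corr_cM = "cM", recomb_rate_cM_Mb = "cM/Mb",
    recomb_rate_cM_pg = "cM/pg", euchromatin_rate_cM_Mb = "cM/Mb",
    genome_size_Mb = "Mb", genome_size_no_ltr_Mb = "Mb",
    gene_density_per_Mb = "genes/Mb",
    compactness_Mb_per_chrom = "Mb/chromosome"
  )
  out
}

#' Compiled trait data for 30 sequenced angiosperm genomes
#'
#' Returns the bundled compilation of published trait values for thirty
#' angiosperm species with sequenced genomes and genetic maps: global and
#' euchromatin-corrected recombination rates (cM/Mb), assembly genome size
#' (Mb), LTR retrotransposon proportions (total, copia, gypsy), gene density
#' (genes/Mb) and average gene family size. `NA` marks traits unavailable
#' for a species.
#'
#' @return A tibble with 30 rows.
#' @examples
#' angiosperm_traits()
#' @export
angiosperm_traits <- function() {
  path <- system.file("extdata", "angiosperm_traits.tsv",
                      package = "recombevol", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Heterochromatin fraction implied by a pair of recombination rates
#'
#' Inverts the euchromatin-correction identity
#' \eqn{\rho_e/\rho = 0.95/(1-h)} to recover the heterochromatin fraction
#' implied by a published (global, euchromatin-corrected) rate pair. A valid
#' pair implies `h` strictly inside `(0, 1)`.
#'
#' @param rate Global rate, cM/Mb.
#' @param euchromatin_rate Euchromatin-corrected rate, cM/Mb.
#' @param map_euchromatic_fraction See [euchromatin_recomb_rate()].
#' @return Implied heterochromatin fraction.
#' @export
implied_heterochromatin <- function(rate, euchromatin_rate,
                                    map_euchromatic_fraction = 0.95) {
  1 - map_euchromatic_fraction * rate / euchromatin_rate
}
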