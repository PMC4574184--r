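# recombevol

Comparative analysis of global meiotic recombination rate evolution and its
genomic correlates across species.

Across flowering plants, the genome-wide ("global") recombination rate — the
total genetic map length over the physical genome size, in cM/Mb — varies by
an order of magnitude, and that variation is entangled with genome
architecture: LTR retrotransposon load, gene density, chromosome number, and
the long-term efficacy of selection on genes. `recombevol` provides the full
analysis chain for studying these relationships in a phylogenetic framework:

* **Recombination rates from linkage maps.** Observed map lengths
  underestimate true genetic lengths when markers are finite; each linkage
  group is corrected by Chakravarti's method-4 factor `(m+1)/(m−1)` (`m` =
  marker count), summed, and averaged over maps
  (`correct_map_length()`, `average_corrected_length()`). Rates are derived
  per Mb, per picogram (C-value), and per euchromatic Mb under the
  assumption that 95 % of the genetic map lies in euchromatin:
  `ρ_e = 0.95 L / (G (1 − h))` (`build_trait_table()`).
* **Phylogenetically corrected correlation.** Felsenstein's independent
  contrasts (`pic_contrasts()`), correlated through the origin with
  `r = Σxy / √(Σx²Σy²)` on k−1 df (`pic_correlation()`,
  `correlate_traits()`), with Kendall's tau and Cook's-distance influence
  diagnostics for sensitivity analysis.
* **Phylogenetic signal.** Blomberg's K with a 999-permutation test on the
  variance of standardised contrasts (`blomberg_k_test()`).
* **Power and meta-analysis.** Cohen's correlation power approximation
  (`correlation_power()`, `required_r_for_power()`) and fixed-effects
  Fisher-z pooling of correlations (`metacor_fixed()`), including the
  C-value ploidy-resampling procedure (`ploidy_metacorrelation()`).
* **Codon composition.** Wright's effective number of codons and GC at
  fourfold-degenerate third positions (`enc()`, `gc3s()`), per species
  (`per_species_composition()`), and average gene family size over
  root-spanning families (`average_gene_family_size()`).
* **Selection screen.** Post-processing of per-gene trait–dN/dS coevolution
  output: ESS convergence filtering, calibration of posterior-probability
  cutoffs to a target significant fraction, sign classification,
  chi-square and Fisher-exact enrichment tests (`coevol_screen()`).
* **Synthetic data.** Seeded generators for Yule trees, correlated
  Brownian-motion traits, finite-marker maps, biased codon sequences, and
  coevolution tables (`simulate_study()`), so every stage is testable
  without external downloads.

All user-facing functions take data frames and return tibbles; fitted
objects have `tidy()`/`glance()` and `autoplot()` methods.

## Worked example

```r
library(recombevol)

# a fully synthetic 30-species study: tree, traits, maps, coevol table
st <- simulate_study(n_species = 30, rho = -0.65, seed = 11)

# recombination rates from the simulated maps (true total: 1200 cM;
# observed totals fall short, the correction recovers them)
head(average_corrected_length(st$maps), 3)
#> # A tibble: 3 x 3
#>   species L_corr_cM n_maps
#>   <chr>       <dbl>  <int>
#> 1 t1          1217.      1
#> 2 t10         1173.      1
#> 3 t11         1235.      1

# phylogenetically corrected correlation of the two planted traits
res <- correlate_traits(st$traits, st$tree, "log_recomb_rate",
                        "log_genome_size")
res
#> Contrast correlation (pearson_origin)
#>   r = -0.7164, p = 8.475e-06, k = 29 contrast pairs
correlation_power(abs(tidy(res)$estimate), n = 30)
#> # A tibble: 1 x 4
#>       r     n alpha power
#>   <dbl> <dbl> <dbl> <dbl>
#> 1 0.716    30  0.05 0.997

# phylogenetic signal of the first trait
blomberg_k_test(st$tree, setNames(st$traits$log_recomb_rate,
                                  st$traits$species), seed = 1)
#> Blomberg's K = 0.8043 (n = 30 tips)
#>   permutation p = 0.001 (999 permutations, contrast_variance statistic)

# calibrated screen of the coevolution table
coevol_screen(st$coevol)
#> Coevolution screen
#>   converged genes: 3556 (dropped 192)
#>   calibrated cutoffs: pp < 0.05258 or pp > 0.9474
#>   significant fraction: 0.050 realized (target 0.050; 0.037 at nominal 0.025/0.975)
#>   significant pool: 148 negative (84%), 28 positive (16%)
#>   sign chi-square (gof_pooled): X2 = 6.84, p = 0.0089
```

The contrast correlation recovers the planted Brownian correlation (−0.65,
estimated −0.72 on this draw), the power annotation says how detectable an
effect of that size is at n = 30, the permutation test detects the
Brownian phylogenetic signal, and the screen's significant pool recovers
the planted 4:1 negative:positive signal mixture while holding the
realized significant fraction at or below its 5 % target.

The bundled `angiosperm_traits()` table (30 sequenced angiosperm genomes;
rates in cM/Mb, sizes in Mb) supports the same workflow on published
values.

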