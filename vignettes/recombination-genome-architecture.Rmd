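---
title: "Methods: recombination rate evolution and genome architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recombination rate evolution and genome architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recombevol)
```

This vignette is the package's account of its methods: the models, the
parameters that matter, the numerical choices, and what the synthetic-data
tests do and do not establish about real data.

## The scientific question

Meiotic recombination shapes genomes on macroevolutionary timescales: it
can purge LTR retrotransposons by unequal crossing over (shrinking
genomes), bias base composition through GC-biased gene conversion, and
relieve Hill–Robertson interference so purifying selection acts more
efficiently on linked genes. Testing these ideas across species requires
(i) comparable per-species estimates of the global recombination rate,
(ii) correlation methods that respect phylogenetic non-independence, and
(iii) a way to summarise per-gene evidence that recombination rate covaries
with *dN/dS*. The package implements each stage.

## Recombination rates from genetic maps

A linkage group genotyped with `m` markers cannot reveal recombination
beyond its terminal markers, so observed map lengths are biased low.
Chakravarti's method 4 corrects each group by `(m + 1)/(m − 1)` before
summing. Two conventions are settled here explicitly:

* `m` counts **markers**, not marker intervals; published map summaries
  report marker counts.
* When several maps exist for one species, each map is corrected with its
  own marker counts and the corrected totals are averaged ("correct, then
  mean"). The alternative order is not equivalent because the correction
  factor is map-specific.

Rates are expressed three ways, each with a distinct error profile:
`cM/Mb` uses the assembly size (biased by unassembled repeats), `cM/pg`
uses flow-cytometric C-values (assembly-independent but ploidy-sensitive),
and the euchromatin-corrected rate
\[
\rho_e = \frac{0.95\, L_{\mathrm{corr}}}{G\,(1 - h)}
\]
assumes 95 % of the genetic map lies in euchromatin (`h` = heterochromatin
fraction). The published description of this correction reads, taken
literally, as physical size over map length — which has units Mb/cM; the
package implements the reciprocal, a cM/Mb rate, the only reading
consistent with the published rate pairs. That reading is checkable: for
every one of the 19 bundled species with both rates, the implied
heterochromatin fraction \(h = 1 - 0.95\rho/\rho_e\) falls strictly inside
(0, 1) — e.g. about 0.77 for tomato, a famously heterochromatic genome —
and feeding it back reproduces the published euchromatin rate to print
precision. Missing values propagate; nothing is imputed.

The bundled `angiosperm_traits()` table carries the published per-species
values (rates, sizes, LTR proportions, gene density, family size).
Haploid chromosome numbers and C-values are not part of the bundle, so
genome compactness (`G / n_chrom`) and the cM/pg pathway are exercised on
synthetic data in the tests.

## Independent contrasts and their correlation

`pic_contrasts()` implements Felsenstein's pruning recursion. Contrast
correlations go **through the origin** with `k − 1` degrees of freedom:
contrasts have arbitrary sign, so a mean term is meaningless; this is the
field-standard contract, and the through-origin slope of contrasts is
algebraically identical to the GLS slope under the Brownian covariance
matrix (asserted to 1e-9 on random trees in the tests). A non-origin
Pearson and Kendall's tau (robust to outlying contrasts) are available as
sensitivity options, as is Cook's distance for the through-origin fit,
which flags sister-pair contrasts that dominate a correlation.

A base-10 logarithmic transform of branch lengths is provided for deep
timetrees whose contrast variances would otherwise be dominated by a few
old splits. The transform requires every branch length to exceed 1 (in
the tree's time unit); a transformed length ≤ 0 cannot standardise a
contrast, and the function errors rather than guessing how sub-unit
branches should be handled.

Missing data are handled by pairwise deletion: each trait pair is analysed
on the species having both traits, with the tree pruned to match. Reported
sample sizes therefore differ across pairs (30 vs 19 species in the
bundled table), which is why power annotations accompany every
correlation.

## Blomberg's K and its permutation test

K is the ratio of the observed MSE ratio (tip variance about the
phylogenetic mean over the phylogenetically corrected MSE) to its
Brownian-motion expectation; K = 1 under Brownian motion, larger under
stronger clustering. The permutation test shuffles tip values (999
permutations by default) and uses the **variance of the standardised
contrasts** as its statistic — lower variance means stronger signal — with
the add-one estimator \(p = (1 + \#\{\mathrm{perm} \le \mathrm{obs}\})/(R+1)\).
Permuting on K itself is available behind an argument. Because contrasts
are linear in tip values, the permutation loop precomputes the contrast
operator once and reduces each permutation to a matrix product.

## Power and meta-analysis

`correlation_power()` follows Cohen's normal approximation as implemented
in the conventional power software: critical r from the t distribution on
n − 2 df, Fisher-z transform with the small-sample bias term
`r/(2(n − 1))` applied to **both** the effect and the critical value, and
normal tail probabilities scaled by `sqrt(n − 3)`. Two conventions were
possible (bias on the effect only, or on both); the both-sides version is
the one that reproduces the published anchors — power 0.98 at (r = 0.65,
n = 30) and a required r of about 0.62 for power 0.8 at 18 contrast
pairs — so it is the default and only version. Its known quirks are
documented in the tests: at the null (r = 0) it is slightly conservative
(power ≈ 0.039 at n = 10 rather than 0.05), and monotonicity in n is
guaranteed only away from r = 0. Against a Monte-Carlo rejection-rate
oracle it is accurate to < 0.02 at moderate n.

`metacor_fixed()` pools correlations on the Fisher-z scale with weights
`n − 3`. `ploidy_metacorrelation()` addresses C-value ambiguity from
within-species ploidy variation: it resamples one C-value per species,
recomputes cM/pg, reruns the contrast correlations against genome size in
pg and in Mb, and pools the replicate correlations; study size per
replicate is the species count (contrast count + 1, keeping every weight
positive). When every species has a single C-value all replicates
coincide and the pooled r collapses to the plain contrast correlation —
a degeneracy the tests assert.

## Codon composition

`enc()` is Wright's effective number of codons from first principles:
per-amino-acid codon homozygosity \(\hat F = (n\sum p_i^2 - 1)/(n-1)\),
class means over synonymous-family sizes {2, 3, 4, 6}, and
\(N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6\), capped at
61. Edge rules are parameterised rather than guessed: amino acids observed
once are dropped from their class mean; a missing isoleucine class is
interpolated as the mean of classes 2 and 4 (Wright's rule); a sequence
missing any of classes 2, 4 or 6 yields `NA`. Note that \(\hat F\) is a
small-sample-corrected estimator, so ENC is exactly invariant to codon
order but only asymptotically invariant to duplicating a sequence.

`gc3s()` counts G/C at third positions of fourfold-degenerate codons. By
default the fourfold subgroups of the sixfold amino acids (Leu CTN, Arg
CGN, Ser TCN) are included — fourfold degeneracy is a property of the
site — with a `strict_fourfold_aa` switch for the five purely fourfold
amino acids.

Average gene family size counts **zeros** for species absent from a
root-spanning family; that is the only convention compatible with
published per-species averages below 1. Families are filtered to those
spanning the root bipartition (present on both sides), and an optional
trim drops the largest families as a robustness check.

## The coevolution screen

Per-gene output of a Bayesian trait–dN/dS coevolution analysis (partial
correlation of recombination rate with *dN/dS* controlling *dS*, its
posterior probability, and ESS diagnostics) is post-processed in four
steps: strict ESS filtering (> 300 for all parameters, > 50 for the root
state); calibration of symmetric posterior-probability cutoffs `(c, 1−c)`
so that at most a target fraction (default 5 %) of genes is significant —
posterior probabilities are not p-values, so FWER/FDR machinery is
deliberately not applied; classification into significant-negative /
significant-positive / nonsignificant-by-sign; and a sign chi-square.
Calibration is conservative ("≤ target", never "closest to target") and
reports the realized fraction alongside the nominal-cutoff fraction. The
chi-square construction is ambiguous in the source analyses (pooled sign
counts vs a significance × sign independence table); both are implemented,
`gof_pooled` is the default, and neither is asserted against any published
statistic.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their parameters and a seed:

* **Yule trees** (forward pure-birth, stopped at the tip count, sampled one
  exponential wait after the last split) — exactly ultrametric and binary,
  with \(E[\mathrm{height}] = \sum_{k=2}^{n} 1/(k\lambda)\) testable
  directly. Default birth rate 0.05/My at 30 species gives root depths of
  order 10^2 My, matching the scale of an angiosperm-wide timetree.
* **Bivariate Brownian traits** with chosen rates and correlation ρ — the
  exact null of the contrast and K machinery.
* **Finite-marker maps**: uniform marker placement, observed length = span
  of the sampled markers. This models only the truncation that the
  Chakravarti correction targets; genotyping error, marker clustering and
  map-function distortions are not modelled.
* **Codon sequences** with a bias parameter interpolating uniform →
  single-codon synonymous usage and a third-position G/C tilt.
* **Coevolution tables**: 95/4/1 % null/negative/positive mixtures with
  Beta(1, 50)/Beta(50, 1) tails and a Uniform(0.05, 0.95) null, the
  published scale of 3748 genes, and a configurable ESS failure rate.

Passing tests on these inputs establishes that the estimators are
implemented correctly and calibrated under their own assumptions. They do
not establish that real angiosperm traits evolve by Brownian motion, that
real maps err only by truncation, or that real posterior probabilities
have a uniform null — those are assumptions of the original analyses, not
conclusions.

## Numerical choices and problem sizes

* Ultrametricity tolerance defaults to 1e-6 relative (the print precision
  of divergence-time software).
* Permutation p-values use the add-one estimator; the permutation count
  is 999 by default and smaller in some tests where the check is about
  calibration, not resolution (199 for the type-I-error sweep, 49–99 in
  unit tests).
* Calibration-style checks in the test suite use 200–600 replicates on
  trees of 30–200 tips; these sizes put Monte-Carlo error comfortably
  inside the asserted tolerances while keeping the default test run
  fast.
* `calibrate_pp_cutoffs()` snaps tail distances `min(pp, 1−pp)` to 12
  decimals so a gene at `pp` and one at `1−pp` cannot be separated by
  floating-point representation error.
* Random draws route through a single seed; replicate streams derive
  sub-seeds by counter, so results do not depend on iteration order.

## Known limitations

* Polytomies are representable but rejected by contrast and K operations;
  no automatic zero-branch resolution is offered, because silent
  resolution changes contrasts.
* PGLS beyond through-origin contrast regression, non-Brownian trait
  models (OU), and ancestral-state reconstruction are out of scope, as are
  alignment construction, ortholog clustering, divergence-time estimation,
  and running the coevolution MCMC itself — the package consumes their
  outputs.
* The power approximation is an approximation: slightly conservative near
  the null and at small n (see the Monte-Carlo comparison in the tests).
* Published headline correlations from any particular study depend on that
  study's tree and supplementary map data; where those inputs are not
  bundled, the package asserts internal-consistency identities (the
  euchromatin round trip) rather than end-to-end reproduction.
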