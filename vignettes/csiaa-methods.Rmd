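---
title: "Methods: amino acid isotope workflows for coral trophic ecology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amino acid isotope workflows for coral trophic ecology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csiaa)
library(dplyr)
```

## The scientific problem

Reef corals are mixotrophs: the animal host draws photosynthates from its
endosymbiotic dinoflagellates (Symbiodiniaceae) and, in parallel, preys on
zooplankton. How much each channel contributes — and how the partners share
heterotrophically acquired nutrients — is hard to resolve with bulk-tissue
isotopes because nitrogen and carbon are recycled intensively inside the
holobiont. Compound-specific isotope analysis of amino acids (CSIA-AA)
resolves this by measuring δ¹⁵N and δ¹³C of individual amino acids in the
separated host and symbiont fractions.

Two ideas carry the analysis:

* **Trophic versus source amino acids (δ¹⁵N).** Glutamic acid is strongly
  ¹⁵N-enriched at each trophic transfer; phenylalanine is nearly inert.
  Their spread yields a trophic position,

  $$\mathrm{TP} = \frac{\delta^{15}\mathrm{N}_{Glu} -
  \delta^{15}\mathrm{N}_{Phe} - \beta}{\mathrm{TDF_{AA}}} + 1,$$

  with β the Glu–Phe offset in primary producers (anchoring TP = 1) and
  TDF the per-level discrimination factor. The packaged constants are
  β = −0.36 ‰ and TDF = 4.54 ‰, the values fitted for
  chloroformate-derivatized measurements; both live in
  `tp_constants()` and can be swapped for other published sets.

* **Essential-AA δ¹³C fingerprinting.** Only primary producers and
  microorganisms synthesise essential amino acids de novo, each with a
  characteristic δ¹³C pattern. The five-AA fingerprint (valine, leucine,
  isoleucine, methionine, phenylalanine) therefore traces the *source* of
  carbon skeletons, compared multivariately (Euclidean distances,
  PERMANOVA, nMDS).

The experimental design the package emulates is a controlled nutrition
study: six mother colonies × three regimes — autotrophy (light, no food),
mixotrophy (light plus *Artemia* feeding), heterotrophy (darkness plus
feeding) — × two compartments (host, symbiont), with the *Artemia* prey
itself as a reference material.

## The instrument layer and its inversion

GC-C-IRMS measurements of amino acids are not directly the tissue values;
three distortions sit in between, and the calibration module inverts each:

1. **Derivatization carbon.** Chloroformate derivatization adds $n_d$
   exogenous carbons per amino acid, so the measured δ¹³C is the
   moles-weighted mixture
   $n_{cd}\,\delta^{13}C_{cd} = n_c\,\delta^{13}C_c + n_d\,\delta^{13}C_{dcorr}$.
   Because certified standards have known underivatized values, each
   standard peak yields the empirical per-AA factor
   `dcorr = (n_cd·δ_cd − n_c·δ_c)/n_d` (`estimate_dcorr()`), averaged over
   the standard blocks at the start and end of the sequence — amino acids
   differ in heteroatoms and functional groups, hence in combustion
   efficiency, so the factor is per-AA and per-sequence. `correct_carbon()`
   then solves the mixing equation for the sample peaks. No nitrogen is
   added by the chemistry, so δ¹⁵N needs no per-AA correction.

2. **Sequence drift.** The instrument response wanders over an injection
   sequence; the certified mix is injected in blocks of three at the start
   and end (and after at most 18 sample injections). `drift_correct()`
   fits a per-element linear model in injection index to the standard
   peaks, with per-AA intercepts absorbing the combustion-level
   differences. For nitrogen the standards' certified values pin the
   absolute level, so both slope and mean offset are removed; for carbon
   the standards are measured as derivatized mixtures whose true level is
   not certified, so only the slope (centred at the mean standard
   injection index) is removed — the residual constant cancels exactly in
   the dcorr estimate. Both paths are verified exact by the zero-noise
   inversion tests.

3. **Nitrogen response.** Combustion and linearity effects are modelled as
   an affine response and removed by one ordinary least-squares fit per
   sequence of certified on measured values across the standard amino
   acids (`calibrate_nitrogen()`); the packaged certified set spans −6.69
   to +43.25 ‰ so samples are interpolated, never extrapolated. The
   regression is fitted certified-on-measured so that applying it is
   direct evaluation; with noise-free standards the two directions are
   identical, and with noise they differ only by fit error.

Replicate injections (duplicates for carbon, triplicates for nitrogen) are
averaged to one value per sample × amino acid × element before the
regression and carbon corrections. Drift correction runs first, at peak
level, because it needs injection indices; since the drift model is linear
in the index, correcting then averaging equals averaging then correcting,
so the averaged-first description and the implementation coincide.

Order of operations: drift → replicate averaging → (nitrogen regression |
dcorr estimation → carbon correction). Whether carbon drift removal
precedes or is folded into dcorr estimation is observationally equivalent;
the package applies drift first and documents that choice here.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws each (sample, amino acid, element) tissue value
independently from Normal(mean, SD) cells of a parameter table;
`forward_instrument()` then applies the three distortions above plus
i.i.d. Gaussian analytical noise and the bracketing-standard sequence
layout. The packaged defaults (`default_parameters()`,
`default_instrument()`) encode the study conditions:

* δ¹⁵N cells for Glu and Phe carry the published group means/SDs
  (e.g. symbiont Glu 3.71 ± 1.23 / 8.49 ± 1.98 / 12.65 ± 2.19 ‰ for
  auto/mixo/heterotrophy; prey Glu 14.17 ± 0.22, Phe 8.03 ± 0.04 ‰).
  Two cells were not published and are anchored interpolations chosen
  once: host Phe 8.0 ± 1.3 ‰ for all treatments (the host/symbiont Phe
  contrast is reported as ≈ 8 vs 4 ‰ and treatment-invariant), and host
  mixotrophic Glu 9.62 ± 1.6 ‰ (midpoint of the published autotrophic and
  heterotrophic host values).
* δ¹³C prey cells are the published *Artemia* table. Tissue cells use a
  −26 ± 1.5 ‰ baseline with the published contrasts imposed: isoleucine
  −18/−21/−22 ‰ (auto/mixo/hetero) and methionine 4 ‰ more negative under
  heterotrophy, in **both** compartments — the published multivariate
  analysis found no host/symbiont separation in the essential-AA
  fingerprint, so compartments share means.
* Instrument defaults: derivatization carbon at −30 ‰ (n_d = 4 for every
  amino acid — the exact chloroformate stoichiometry is reagent-specific
  and overridable per AA in the chemistry table), drift 0.02/0.03 ‰ per
  injection (C/N), analytical SD 0.3/0.5 ‰ (C/N, typical GC-C-IRMS
  amino-acid precision), nitrogen response intercept −0.6, slope 0.985,
  standard blocks of 3 bracketing ≤ 18 sample injections, duplicate C /
  triplicate N injections. The certified δ¹³C values and the five unnamed
  certified δ¹⁵N values in `default_standards()` are synthetic
  placeholders with realistic magnitudes; alanine (+43.25 ‰) and valine
  (+30.19 ‰) carry their published certified values.

Deliberate simplifications: draws are independent across amino acids
within a sample, so baseline (colony) variation shared between Glu and Phe
is not represented — per-sample TP is therefore *more* variable than in
the real study, where the shared baseline cancels in the Glu−Phe
difference (printed group TP SDs ≈ 0.22 versus ≈ 0.5–0.6 here). An
optional per-colony random intercept (`colony_sd`) exists but defaults to
0 because no variance component was published; enabling it adds shared
variation on top of the marginal SDs rather than re-partitioning them.
There is no chromatographic peak-shape, size-effect nonlinearity or
per-AA drift modelling. Consequently, passing tests demonstrate that the
*estimators* recover the *generator's* truth under the published group
structure — not that real chromatograms are this well behaved.

## Statistical battery

Matching the study's analysis plan: δ¹⁵N variables are compared with
Kruskal–Wallis plus pairwise Wilcoxon rank-sum post hocs under
Benjamini–Hochberg adjustment (the variables fail the
variance-homogeneity checks reported by `variance_checks()`; Bartlett's
test is reported in its standard role as a variance test). δ¹³C variables
are compared per amino acid with an additive two-way ANOVA (sequential SS,
treatment entered before compartment) and Tukey HSD, and multivariately
with Euclidean PERMANOVA and nMDS restricted to the
autotrophy/heterotrophy contrast — the mixotrophic δ¹³C values are
reported as too colony-variable to separate, and the residual degrees of
freedom of the published ANOVA tables indicate two treatments. The
treatment subset is an argument (`carbon_treatments`) so users can include
mixotrophy.

PERMANOVA is implemented in-package (Gower-centred squared-distance
matrix, sequential hat-matrix partitioning, pseudo-F against the residual,
free row permutation without strata, observed configuration counted in
numerator and denominator). The permutation count defaults to 999;
sub-1e-10 sums of squares are clamped to zero so degenerate
perfect-separation toys give exact 0/∞ rather than numerical dust. Tests
cross-check the implementation against `vegan::adonis2` to 1e-8 and
against exhaustive label enumeration on six-sample toys, and verify null
p-value uniformity. nMDS delegates to `vegan::metaMDS` (20 random starts
plus a metric start, best stress kept, seed recorded); rank tests delegate
to the standard R routines — the tests assert hand-computed oracles
(H = 7.2 on 1–9 split into thirds; BH step-up by explicit cumulative
minimum) rather than re-deriving those procedures.

## Numerical and design choices

* Zero-noise inversion is asserted at 1e−9 ‰ (it achieves ≈ 1e−14);
  noisy recovery at 3 standard errors.
* Seeds are mandatory for every stochastic stage; `run_pipeline()` derives
  per-stage sub-seeds from one master seed, and the generator
  saves/restores the caller's RNG state.
* Tie handling in rank tests follows the midrank convention; Wilcoxon
  p-values are exact for small tie-free samples, normal-approximate
  otherwise.
* Degenerate inputs are reported, not hidden: constant responses give
  zero F statistics with NA p-values, all-identical Kruskal–Wallis input
  gives p = 1 with a warning, single-replicate SDs are NA, n_d = 0 makes
  the derivatization factor an explicit error, and a sequence with fewer
  than two standard blocks skips drift correction with a warning.
* The cohort validator reports design balance and missing cells but does
  not enforce an expected sample count — published residual degrees of
  freedom suggest the real dataset contained more observations than the
  nominal design, so enforcement would be wrong.

## Problem sizes

The test-suite and reproduction script sizes are chosen to make Monte
Carlo error negligible relative to the tolerances while keeping a full
run on one CPU in minutes: parameter-recovery checks use 500 samples per
group (3·SD/√500 windows), calibration inversion is property-tested over
100 random instrument draws, null-calibration checks use 1000 simulated
datasets with 199 permutations each, and the qualitative-pattern checks
run the full six-colony pipeline over five seeds with 999 permutations.

## Known limitations

* The trophic-position model is the single-TDF Glu/Phe form; multi-AA
  weighted TP estimators are out of scope.
* Group comparisons treat samples as independent; the repeated use of the
  same six mother colonies across treatments is not modelled as a random
  effect (none was published to calibrate against).
* The generator's independence assumption overstates TP variance (see
  above); bound-style checks on group-mean TP are robust to this, but
  per-sample TP dispersion is not comparable to the real study's.
* Real GC-C-IRMS sequences lose peaks; the reader rejects malformed rows
  loudly and `compute_tp()` drops incomplete samples with a warning, but
  no imputation is attempted.
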