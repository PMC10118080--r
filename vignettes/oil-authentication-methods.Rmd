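---
title: "Methods: metabolomic marker discovery and authentication of seed oils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolomic marker discovery and authentication of seed oils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oilmarkr)
```

## The problem

Cold-pressed sesame and flaxseed oils sell at a premium over sunflower and
rapeseed oil, which makes undeclared substitution or dilution financially
attractive and, for allergen-carrying oils such as sesame, a health hazard.
`oilmarkr` implements an untargeted LC-QTOF-MS workflow for authenticating
four seed oils (sunflower, rapeseed, sesame, flax): molecular features are
aligned across runs, filtered, modelled with OPLS-DA, and screened against a
negative panel of other oil species to yield ions that occur in every sample
of exactly one species. Those ions — 29 in the packaged library: 13 for
sunflower, 8 for rapeseed, 5 for sesame, 3 for flax — are then used as
qualitative markers: an oil declared as sesame should show all five sesame
markers, and a 1–5% (v/v) admixture of a foreign oil can be detected from the
appearance of that oil's markers.

The package also implements the accompanying bioactivity endpoints (ABTS
radical scavenging expressed as Trolox equivalents, Folin-Ciocalteu total
phenolics, total carotenoids) and their comparison statistics (one-way ANOVA
with Tukey HSD homogeneous-group letters computed from replicate summaries).

No instrument data are required anywhere: a synthetic-data module generates
feature tables, mixtures, blanks and assay plates with the statistical
structure the analysis assumes, so every stage of the pipeline is testable
end to end.

## Feature alignment and filtering

A molecular feature is a triple (m/z, RT, height) plus a deconvolution
quality score. Features from different runs are grouped into consensus
compounds with combined relative + absolute tolerance windows:

* mass half-width at m/z $m$: $m \cdot \mathrm{ppm} \cdot 10^{-6} +
  \mathrm{mDa}$, default 5 ppm + 2.0 mDa;
* RT half-width at RT $t$: $t \cdot r + a$, default 0.1% + 0.15 min.

Alignment is greedy seeded clustering: features are pre-sorted canonically
(descending height, then m/z, RT, sample id — so the result is invariant to
input order), each unassigned feature seeds a consensus, and the seed absorbs
every unassigned feature whose window *overlaps* its own, i.e.
$|\Delta m/z| \le hw(\mathrm{seed}) + hw(\mathrm{candidate})$, with at most
one feature per sample (ties broken by smallest $|\Delta m/z|$, then
$|\Delta RT|$, then canonical order). Consensus coordinates are
intensity-weighted means. The overlap (sum-of-half-widths) form is the one
under which the intended merge behaviour is self-consistent: with
single-half-width matching, two features each within tolerance of a common
centre could be mutually unmergeable. On small, well-separated instances the
greedy partition coincides with exhaustive single-linkage clustering; the
test suite verifies this against a connected-components oracle.

Filtering follows the reference processing settings, all inclusive
thresholds: peak height ≥ 600 counts, quality score ≥ 80 ("Filter by
Flags"), and per oil species a frequency filter that keeps compounds found
in *all* samples of the species ("Filter by Frequency"). Consensus features
detected in any solvent blank are removed. The vendor-style "compound
absolute count" limit of 50,000 counts is implemented as a per-sample QC
gate on the summed feature height before alignment: applied per feature it
would contradict the 600-count peak floor and delete genuine low-abundance
markers. Missing values are encoded as 0, matching the detection-floor
semantics of the simulator.

## Chemometrics

Variables are mean-centred and Pareto-scaled ($x' = (x - \bar{x}) /
\sqrt{s}$); zero-variance variables cannot be scaled and are dropped with a
warning. PCA uses NIPALS with per-component $R^2X_a = \|t_a p_a^T\|^2 /
\|X\|^2$.

OPLS-DA dummy-codes the species labels into a 0/1 matrix $Y$ (one column per
class; prediction assigns the class with the largest predicted membership)
and proceeds in two stages:

1. **Orthogonal filtering.** Let $B$ be an orthonormal basis of the column
   space of $X^TY$. For each of $O$ orthogonal components, a NIPALS PLS
   component of the current residual is computed, its X-loading is projected
   off $B$ and normalised to give the orthogonal weight $w_o$; since
   $w_o \perp X^TY$, the orthogonal score $t_o = Xw_o$ is *exactly*
   uncorrelated with every class column. $X$ is deflated by $t_o p_o^T$.
2. **Predictive model.** A NIPALS PLS2 model with $A$ predictive components
   is fitted on the filtered matrix.

Component counts follow the "A+O+0" notation (A predictive, O X-orthogonal,
no Y-orthogonal components); the pipeline default is `n_classes - 1`
predictive (3 for four oils) plus 2 orthogonal. For degenerate inputs whose
scaled matrix has rank below $A+O$ (e.g. noise-free simulations, where the
rank is exactly `n_classes - 1`), the pipeline clamps the orthogonal count
to the rank rather than failing.

Reported statistics:

* $R^2X$ per component and cumulative over both blocks; $R^2Y = 1 -
  \mathrm{RSS}/\|Y_c\|^2$;
* $S^2Y$ — residual class-matrix variance, $\mathrm{RSS} / ((N-1) k)$ for
  $k$ classes (the per-column mean residual variance);
* $SEE = \sqrt{\mathrm{RSS}/(N - A - O - 1)}$ — root-mean-square error of
  estimates with a degrees-of-freedom correction for all fitted components
  (the definition leaves the df convention open; this one is recorded here
  as the package's choice);
* $Q^2 = 1 - \mathrm{PRESS}/\mathrm{SS}$ from 7-fold venetian-blind
  cross-validation (sample $i$ in fold $(i-1) \bmod 7 + 1$), with centring
  and scaling re-estimated inside every training fold so no information
  leaks; `n_folds = N` gives leave-one-out, verified against brute-force
  refits;
* permutation validation: class labels are permuted `n_perm` times (default
  200) and $p = (1 + \#\{Q^2_{perm} \ge Q^2_{obs}\})/(n_{perm}+1)$, bounded
  below by $1/(n_{perm}+1)$.

**VIP normalisation.** VIP scores are computed over the predictive
components and normalised over *all* variables submitted to the model, with
dropped zero-variance variables counting as VIP 0. Standard VIP renormalises
over the retained variables only, which makes the score of an informative
variable depend on how many constant columns accompany it; in the noise-free
limit, where every uninformative background column is constant and dropped,
that convention forces the mean squared VIP of the informative survivors to
1 and no fixed threshold can behave consistently across noise levels. With
the convention used here, VIP is identical to the standard definition
whenever nothing is dropped.

**Contributions.** The per-class contribution of a variable is the
class-mean predictive score vector back-projected through the loadings —
the model-explained elevation or depletion of that variable in the class, in
scaled units. Marker candidates must be detected in every target-class
sample, absent from every negative-panel sample, and carry VIP ≥ 1.5
(configurable; the threshold plays the role of the visual contribution-plot
inspection in the manual workflow).

## Targeted screening and mixtures

`screen_sample()` matches a feature list against the marker library: a hit
requires the precursor within the mass window and the RT within
`rt_tol * 3` of the library value (the library's RT spread is treated as one
spread unit; the multiplier covers batch drift and is configurable). MS/MS
confirmation is optional — screening is MS1-only by default, and
`min_fragments` can demand ≥ k of the five library fragments. A sample is
"authentic-consistent" when all markers of its declared species are present.

`mixture_detection_table()` evaluates detectability of markers after
volumetric dilution: each bottle of the minor oil is mixed into a carrier
oil (sunflower into rapeseed; the other oils into sunflower, matching the
study design), heights scale with the volume fractions, co-eluting features
are summed, the detection floor is re-applied, and the mixture is screened.
A marker counts as detected if any bottle's mixture shows it. Abundance
variability of a marker is reported as $100 (\max - \min)/\max$ over the
samples where it was detected — the "difference between the highest and
lowest signal" as a percentage of the highest; a single detected sample
gives 0 and an undetected marker is reported missing.

## The synthetic-data generator

The generator emulates the study layout: 4 species × 4 producers (a–d) × 2
bottles = 32 oil samples, five marker-free panel species (pumpkin, evening
primrose, black cumin, hemp, thistle) with the same layout (40 samples; the
negative panel for one oil is the other three oils plus these five, 64
samples), three solvent blanks, and two-component v/v mixtures.

Intensity model, chosen once and fixed:

* **Markers** (from the packaged library): height = base × producer factor ×
  batch factor, factors lognormal with `producer_log_sd = 0.5` and
  `batch_log_sd = 0.2`, drawn per marker — this reproduces max–min
  abundance differences across the eight samples of a species mostly in the
  reported 47–89% band. Base intensities are free parameters constrained by
  the mixture flags: markers flagged detectable at 1% get 120,000 counts,
  the rest 30,000, so with the 600-count floor the flags emerge exactly at a
  mixing fraction of 0.01 (noise-free boundary at 600/0.01 = 60,000).
* **Background** (500 compounds, lognormal bases around 50,000 counts) is
  the common seed-oil metabolome: expressed by *all four* target oils
  (panel species express a random 80% share). Its intensities rise and fall
  together through a global per-producer and per-bottle factor shared
  across species, plus per-compound scatter (`batch_log_sd`). This puts
  correlated, class-neutral structure into X — precisely the variation the
  orthogonal OPLS-DA components are there to strip — while leaving the
  class signal to the planted species-specific compounds.
* **Species-distinguishing non-markers** (15 per target species, bases
  around 40,000 counts): expressed by their species and by two panel
  species. They mimic the class-informative ions that a negative-panel
  screen rejects as shared — the reason the panel step exists — and they
  are necessary for the model-quality regime: with only 29 informative
  variables (flax has just 3 markers) a class matrix cannot be regressed to
  the R²Y ≈ 0.99 / Q² ≈ 0.98 level the method is known to reach on real
  profiles.
* **Measurement noise**: m/z error Gaussian with 1.5 ppm SD (well inside the
  5 ppm + 2 mDa window), RT jitter Gaussian with 0.05 min SD (so three RT
  spread units of even the sharpest library marker stay beyond 4 SD);
  heights below 600 counts are censored. Solvent blanks carry 30 contaminant
  compounds kept outside a guard zone (10 mDa, 0.6 min) of every planted
  compound, as are background and species-specific compounds relative to
  markers, so planted identities remain unambiguous for validation.

A ground-truth manifest (planted identities, pre-censoring heights) is
stored alongside the data and read only by tests, never by the pipeline.
Identical seeds give bit-identical datasets.

**What the generator does not emulate:** isotope patterns and adducts,
chromatographic peak shapes, RT drift trends, species-dependent intensity of
shared compounds, and correlated marker co-regulation within a species. Tests
passing on this generator therefore demonstrate that the pipeline recovers
the structure it assumes — not that it would survive every artefact of real
instrument data; in particular, the background's exact class-neutrality is
an idealisation under which the exclusivity screen, not the model, is what
guards against species-dependent background.

Assay plates are simulated from the stated measurement models — linear
calibration for total phenolics (gallic acid standards, 25–200 µg/ml) and
carotenoids (β-carotene, 5–500 µg/ml), a Hill dose-response for ABTS — with
multiplicative Gaussian absorbance noise, so the reduction functions recover
the planted truth exactly at zero noise.

## Bioassays

`%Reduction = (A_c - A_s)/A_c × 100`. EC50 is estimated by fitting a
four-parameter logistic curve and solving for 50% reduction (root-finding on
the fitted curve, tolerance 1e-12); if the fit fails the estimate falls back
to interpolating between the two bracketing points, in concentration space —
linear rather than log-linear, so an exactly linear dose-response gives the
exact answer and a zero-concentration anchor point is usable. The response
must bracket 50% and increase with concentration. TEAC is the ratio of the
Trolox EC50 (mg/L of assay volume) to the sample EC50 (kg oil/L), which
lands directly in mg Trolox per kg oil; analogous unit bookkeeping (dilution
factor, g oil per ml extract) converts curve inversions to mg analyte per kg
oil for the two linear assays.

ANOVA and Tukey HSD are computed from per-group summaries (mean, SD, n) —
the form in which replicate data are reported — with the pooled error mean
square $\sum (n_i - 1)s_i^2 / \sum (n_i - 1)$ and Tukey–Kramer studentized
range statistics at the pooled df. Homogeneous groups are lettered by
insert-and-absorb, which guarantees the compact-letter-display property:
two groups share a letter exactly when their Tukey p ≥ α (default 0.05).
Letters are assigned in descending order of the group means. The test suite
cross-checks the pairwise p-values against `aov()` + `TukeyHSD()` on raw
replicates reconstructed to the same means and SDs. With summary statistics
the letters can differ in borderline pairs from those computed on the
original raw readings (rounded means/SDs shift p-values near α); the
reproduced structure is assessed at the level of pairwise share/not-share
concordance.

## Numerical choices and degenerate inputs

* NIPALS convergence: relative score change below 1e-16, ≤ 2000 (PLS) /
  5000 (PCA) iterations — tight enough to match SVD and two-block PLS
  oracles to 1e-6.
* Zero-variance columns: dropped with a warning before modelling (VIP 0).
* Rank-deficient fits: requested components beyond the matrix rank are an
  error in `fit_oplsda()`; the pipeline clamps the orthogonal count instead.
* Tukey with a zero pooled MSE: pairs with different means are significant
  (q = ∞), identical means are not.
* EC50 with MSE-degenerate or short inputs: interpolation fallback as above.
* `filter_frequency(min_fraction = 0)` is the identity on detected features;
  censoring is monotone (raising the floor never adds a feature); mixture
  scaling is linear in the fraction before censoring.

## Problem sizes

The shipped defaults are the study conditions: 32 oil + 40 panel samples +
3 blanks, 589 planted compounds per the counts above. The test suite runs
the full pipeline repeatedly (20 seeds for the noisy-recovery check) and
uses reduced designs (40–100 background compounds) where a full-size run
adds nothing to the property under test. Monte-Carlo assay recovery uses
500 seeds (200 for the slower dose-response fits); the permutation test in
the acceptance script uses 49 permutations, and the package default is 200.

## Known limitations

* OPLS-DA is implemented for the multi-class dummy-Y case used here; no
  Y-orthogonal (O2PLS-style) components.
* The CEF reader supports the minimal feature-list dialect (m/z, RT, height,
  quality), not the full vendor schema.
* Quantitative estimation of the adulteration level is out of scope — marker
  abundances vary several-fold across producers and batches, so markers are
  qualitative evidence only.
* Compound identities are not assigned; markers are anonymous (m/z, RT,
  fragment) signatures, and database annotation is out of scope.
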