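---
title: "Calibrating serum retinol from EEM fluorescence: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating serum retinol from EEM fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(serumEEM)
```

## The measurement problem

Vitamin A status of fattening cattle is monitored through serum retinol,
conventionally quantified by HPLC after solvent extraction — accurate but
slow and costly per sample. Excitation-emission matrix (EEM) fluorescence
of untreated serum offers a rapid alternative: a single front-face scan
over a 250–450 nm excitation by 250–600 nm emission grid (5 nm and 1 nm
steps; 41 × 351 cells) captures the intrinsic fluorophores of serum, and
chemometric models can extract the retinol-related part of that signal.
serumEEM implements that whole chain: the EEM data model, scatter
handling, trilinear decomposition (PARAFAC), and PLS calibration with the
evaluation metrics customary in spectroscopic calibration.

Because no public cattle-serum EEM dataset with HPLC references exists,
the package ships a synthetic generator with known ground truth, and every
claim the test suite makes is a claim about recovery of that truth.

## Models

### Trilinear decomposition

A stack of $K$ scans is modelled as

$$x_{ijk} = \sum_{f=1}^{F} b_{if}\, a_{jf}\, c_{kf} + e_{ijk},$$

with $b_f$ an emission profile, $a_f$ an excitation profile and $c_{kf}$
the amount of fluorophore $f$ in scan $k$. Fitting is alternating least
squares: each mode in turn is updated by columnwise (hierarchical)
least-squares sweeps with projection to the nonnegative orthant — spectra
and concentrations are physically nonnegative, and the constraint also
stabilises the decomposition, as is standard practice for EEM data.
Because the gram matrix and cross-product are fixed while one mode is
optimised, the columnwise sweeps are repeated (up to 10 times) per mode per
iteration; this costs almost nothing — the cross-products dominate — and
substantially accelerates convergence when spectral profiles overlap, as
the three protein-like serum bands do.

Unconstrained modes use the exact joint block solve instead (the update
has a closed form), which converges much faster when components are
collinear. Missing cells (excised scatter) are handled EM-style: each
sweep imputes them from the current model, so the observed-cell residual
sum of squares is non-increasing across sweeps, a property the tests
assert on every fitted trace. Convergence is declared when the relative
change of that residual falls below `rel_tol` (default 1e-8, `max_iter`
2500). The first start is initialised from the leading singular vectors of
the three unfoldings (magnitudes, respecting nonnegativity); further
seeded random starts (default 10 in total) guard against local minima,
the best final fit winning with ties broken by iteration count.

The rank scan deserves care on serum data: the three protein-like bands
overlap strongly (emission congruence ~0.98), and a cold-started fit at
the true rank routinely spends its extra component refining the dominant
protein subspace — a local minimum — instead of extracting the retinol
band, which is four orders of magnitude dimmer. `select_n_components()`
therefore warm-starts each candidate from the previous rank's solution
plus one random component (`warm_start = TRUE`), and rank scans are best
run without nonnegativity constraints, which are known to inflate core
consistency; the final model at the chosen rank is then refit with the
constraints on.

The number of components is chosen with the core consistency diagnostic:
the least-squares Tucker core of the data given the fitted loadings is
compared with the superdiagonal identity the trilinear model implies, and
the largest candidate holding at least 60% core consistency (a common
working threshold) with a non-degenerate solution (no component pair with
Tucker congruence above 0.95 in both spectral modes) is selected. Cattle-serum
EEMs resolve into about four components (three protein-like, one
retinol-related) without an obvious a-priori criterion for the count; the
core-consistency rule is this package's documented criterion, and on
four-fluorophore synthetic stacks it recovers exactly four.

### Scatter handling

Three non-trilinear ridges contaminate serum EEMs: first-order Rayleigh
(em = ex), second-order Rayleigh (em = 2·ex), and the water Raman band at
an energy shift of ~3400 cm⁻¹, whose emission centre for excitation
wavelength $\lambda_{ex}$ (nm) is $1/(1/\lambda_{ex} - 3400\cdot10^{-7})$.
Default half-widths are 15 nm for both Rayleigh orders and 10 nm for the
Raman band — typical EEM-preprocessing values; instrument vendors ship
their own proprietary scatter filters with undocumented settings, so all
widths are configurable. Before PARAFAC the ridge cells are excised (the masked ALS
handles the holes); before PLS they are linearly interpolated along the
emission axis, because the regression needs a dense matrix.

### PLS calibration

The processed stack is unfolded to a samples × 14391 matrix
(excitation-major column order, recorded in a variable map so coefficient
and VIP vectors can be refolded into contour maps), unit-variance scaled
(sample sd, $n-1$ denominator; zero-variance columns dropped and
recorded), and regressed on the reference concentrations with NIPALS PLS1.
The number of latent variables is chosen from
$Q^2 = 1 - \mathrm{PRESS} / \mathrm{SS}_{tot}$ under seeded 7-fold
cross-validation (folds stratified by response quantile), taking the
smallest count within 0.01 of the maximal $Q^2$ — a parsimony rule: a
latent variable is only kept when it buys a non-negligible gain in
predictive ability. Cross-validation
operates on the once-scaled calibration matrix; scaling is not
re-estimated inside folds. Validation rows are always scaled with the
calibration parameters.

Reported metrics follow spectroscopic-calibration conventions:
$R^2$ is the squared Pearson correlation of observed versus predicted
(the $1-\mathrm{SSE}/\mathrm{SST}$ variant is reported alongside as
`r2_alt`), RMSEE uses the $(n - 1 - A)$ denominator, RMSEP the plain mean
square, and RPD is the validation reference standard deviation over RMSEP,
banded as: below 1.5 preliminary screening, 2.0–2.5 satisfactory, above
2.5 good — the 1.5–2.0 gap this convention leaves open is labelled
"intermediate".

Variable importance in projection is
$\mathrm{VIP}_j = \sqrt{p \sum_a w_{ja}^2\,\mathrm{SSY}_a / \sum_a
\mathrm{SSY}_a}$, normalised so the mean squared VIP is exactly 1;
variables above 1 are flagged important. Peaks of the refolded VIP map are
its local maxima above 1, merged within a 15 nm (ex) × 30 nm (em)
neighbourhood — wide enough to suppress grid-level jitter while keeping
the free-retinol and protein-bound-retinol bands separate.

## The synthetic serum generator

`simulate_dataset()` emulates the reference study design: 208 samples × 3 analytical
replicates on the instrument grids, concentrations from a truncated normal
(mean 46.7, SD 25.8, range 11.0–124.0 IU/dl — the calibration-set
descriptive statistics), and serum fluorescence as a trilinear mixture of
five Gaussian-band fluorophores at the serum band positions: three
protein-like components (285/342 dominant, 300/350, 270/320 nm) with
lognormal amounts (sd 0.25 on the log scale) deliberately uncorrelated
with retinol — so the pipeline cannot shortcut through protein signal —
plus the free-retinol band (325/447, amount equal to the concentration)
and the retinol-binding-protein band (330/520, amount
0.6 × concentration with a small seeded scatter, sd 2). Band widths
default to 18 nm (ex) and 28 nm (em): fluorescence bands are broad, and
these widths let the protein components overlap realistically while
remaining resolvable.

Two generator choices deserve explanation:

* **Brightness.** Per unit amount: 1000 / 400 / 250 for the protein
  components, 0.35 for free retinol, 0.5 for the RBP band. This puts the
  retinol band near 1–2% of the tryptophan signal, so retinol is invisible
  in raw contour plots — as in real serum scans, where no retinol peak
  can be confirmed by eye before decomposition — yet cleanly extractable
  by PARAFAC and PLS.
* **Noise anchor.** Additive noise is `noise_sd` (default 2%) of the
  median *signal-bearing* cell (cells above 1% of the stack maximum). Most
  of an EEM is empty, so the plain all-cell median would sit near zero and
  make the relative setting meaningless; anchored to actual signal the
  default yields a realized noise sd of roughly 4 intensity units —
  per-cell SNR around 4 at the retinol band maximum and around 500 at the
  tryptophan maximum, plausible for a fast plate-reader scan. Replicates
  additionally carry a 1% multiplicative jitter.

What the generator does **not** emulate: inner-filter effects,
photobleaching, wavelength-dependent detector response, additional serum
fluorophores (NADH, bilirubin, ...), or covariate structure (age, sex,
feeding). Passing recovery tests therefore demonstrates correctness of
the algorithms under the stated generative model, not instrument-grade
performance on real serum.

## Numerical choices and degenerate inputs

* Grids are validated to be inclusive arithmetic sequences; non-divisible
  ranges are errors, a single-point grid is allowed.
* All-zero tensors and component counts exceeding any mode are errors;
  non-convergence is reported via `converged = FALSE`, not an exception.
* A dead (all-zero) component column during the nonnegative sweeps is
  revived with a tiny constant so the factor matrix keeps full width.
* Loading argmax ties (flat profiles) resolve to the lowest wavelength.
* PLS truncates to the attained rank, with a flag, when a score norm
  collapses; RMSEE requires $n_{cal} > A + 1$; an RMSEP of zero flags RPD
  as infinite rather than failing.
* Every stochastic step (starts, splits, folds, permutations, the
  generator) is seeded, and the pipeline derives stage seeds from one
  master seed, so reruns reproduce every numeric field exactly.

## Problem sizes used in the test suite

The suite exercises the full 41 × 351 × 624 design where the claim is
about that design (stack dimensions, component-count selection, the
calibration-quality band), and reduced designs (coarser grids, 6–60
samples) for algorithmic properties that are size-independent —
orthogonality, monotonicity, core consistency, fold/scale identities.
Full-stack PARAFAC rank scans use a lighter fitting configuration (one
warm-started run per candidate, 250 sweeps, `rel_tol` 1e-7, no
nonnegativity) than the module defaults; tighter settings change the
runtime, not the selected component count.

## Known limitations

* The permutation test's $R^2$ intercept is uninformative for this data
  shape: with ~12k scaled variables and 145 calibration samples a
  multi-component PLS fits any permuted response almost perfectly in
  training, so the intercept saturates near 1 regardless of model
  validity. The $Q^2$ intercept remains the meaningful criterion (about
  −0.15 on default synthetic data) and is the behaviour reported for comparable
  wide-matrix serum calibrations. On narrower matrices (p < n) both intercepts
  behave classically, which is what the unit tests assert.
* Core consistency is computed from a single fit per candidate; split-half
  validation is deliberately out of scope.
* The replicate policy for PLS defaults to averaging the three analytical
  replicates per sample before calibration; the alternative of using every
  scan as a row (reference values inherited within sample) is available
  via `replicate_policy = "all"`. Either convention is defensible;
  averaging makes the validation unit the sample, which is the quantity a
  practitioner predicts.
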