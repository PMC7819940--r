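# serumEEM

Chemometric calibration of **serum retinol concentration from
excitation–emission matrix (EEM) fluorescence** of untreated serum.

Vitamin A status of fattening cattle is routinely monitored through serum
retinol, conventionally measured by HPLC after solvent extraction. A single
front-face EEM scan of raw serum (excitation 250–450 nm / 5 nm steps,
emission 250–600 nm / 1 nm steps) takes minutes and no reagents; the retinol
signal it contains is far too weak to read off the raw contour plot, but it
can be extracted statistically. serumEEM implements the full extraction
chain as a tested R package:

* **EEM data model** — wavelength grids, single scans, replicate stacks,
  strict CSV readers/writers, folding/unfolding between the three-way array
  and the sample × variable matrix used for regression.
* **Scatter handling** — excision or emission-axis interpolation of the
  first/second-order Rayleigh ridges and the water Raman band
  (`em = 1/(1/ex − shift·10⁻⁷)`, shift 3400 cm⁻¹).
* **PARAFAC** — trilinear decomposition
  `x[i,j,k] = Σ_f em[i,f]·ex[j,f]·score[k,f]` by alternating least squares
  (nonnegativity constraints, SVD or warm-start initialisation, multiple
  seeded starts, EM handling of missing cells), component-count selection by
  the core consistency diagnostic (CORCONDIA), peak localisation, and
  score–reference correlation.
* **PLS calibration** — NIPALS PLS1 on the unit-variance-scaled unfolded
  stack, latent-variable count by seeded 7-fold cross-validated Q² with a
  parsimony rule, prediction, R²/RMSEE/RMSEP/RPD metrics
  (`RPD = sd(y_val)/RMSEP`; > 2.5 read as good prediction), VIP scores
  (`mean(VIP²) = 1`; VIP > 1 flags important wavelength pairs), coefficient
  and VIP contour maps with peak extraction, and Y-permutation validation.
* **Synthetic serum generator** — trilinear mixtures of Gaussian-band
  fluorophores at the serum band positions (three protein-like bands,
  free retinol at 325/447 nm, RBP-bound retinol at 330/520 nm), Table-1
  concentration statistics (truncated normal, 46.7 ± 25.8, range 11–124
  IU/dl), three analytical replicates, additive noise and optional scatter
  ridges, with exact ground truth for recovery tests.
* **Pipeline + CLI** — `run_pipeline()` orchestrates
  simulate/load → preprocess → PARAFAC → PLS → JSON report + CSV artifacts;
  a thin wrapper script lives at `inst/cli/serum-eem`.

## Worked example

```r
library(serumEEM)

# the full synthetic study: 208 samples x 3 replicates on the instrument
# grids, split 145/63, averaged replicates, CV-chosen latent variables
report <- run_pipeline(pipeline_config(
  mode = "simulate",
  sim  = serum_sim_config(seed = 1),
  parafac = list(enabled = FALSE),
  pls  = list(permutation = FALSE),
  seed = 1))
print(report)
```

```
<run_report>
  PLS: A = 2, R2_val = 0.993, RMSEP = 1.93 IU/dl, RPD = 11.36 (good)
```

The validation R² of 0.993 is the squared Pearson correlation between
predicted and true retinol concentrations of the 63 held-out samples; the
RPD of 11.4 (validation reference SD over RMSEP) sits far above the 2.5
threshold for "good prediction". The VIP map of the same model peaks at
(330, 454) and (335, 529) nm — within one band-width of the generator's
free-retinol (325/447) and RBP-bound (330/520) bands, the two wavelength
regions a practitioner would read off the importance plot.

PARAFAC extracts the four spectrally distinct serum fluorophores. Serum
spectra overlap strongly, so the reliable route is the two-step one the
pipeline uses internally: an unconstrained rank scan, then a nonnegative
refit warm-started from the scan's solution:

```r
ds   <- simulate_dataset(serum_sim_config(seed = 1),
                         default_fluorophores()[1:4])
scan <- select_n_components(ds$stack, 2:5,
  config = parafac_config(nonneg = c(FALSE, FALSE, FALSE), n_starts = 1,
                          max_iter = 250, rel_tol = 1e-7, seed = 1))
m <- fit_parafac(ds$stack, as.integer(scan),
                 parafac_config(n_starts = 1, max_iter = 300, seed = 1),
                 init_factors = attr(scan, "model"))
component_peaks(m)
#>   component  ex  em
#> 1         1 285 342
#> 2         2 300 349
#> 3         3 270 320
#> 4         4 325 447
```

with the fourth (retinol) component's scores correlating r = 0.999
(P < 0.001) with the true concentrations — the generator's bands sit at
285/342, 300/350, 270/320 and 325/447 nm.

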