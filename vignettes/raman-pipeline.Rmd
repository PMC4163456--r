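---
title: "Methods: Raman spectral discrimination of tumor and normal tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Raman spectral discrimination of tumor and normal tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramandx)
```

## The problem

Infiltrative gliomas have no sharp margin, which makes the resection border
hard to judge intraoperatively. Raman microspectroscopy reads out vibrational
band intensities — protein C–C and amide III, lipid C–C and CH~2~, nucleic
acid O–P–O — that run systematically higher in tumor cells and tissue than in
their normal counterparts. `ramandx` implements the full analysis chain that
turns raw spectra into (i) per-wavenumber differential statistics with a
permutation false discovery rate, (ii) out-of-sample tumor probabilities from
an L2-penalized logistic model under leave-group-out cross-validation, (iii)
PCA cluster visualizations, and (iv) band-intensity chemical maps — together
with a synthetic-spectrum generator that makes every stage testable without
access to any instrument data.

## Preprocessing model and its choices

Each spectrum passes through: cosmic-ray despiking, baseline subtraction,
normalization to the phenylalanine band, cropping to the 580–1800 cm^-1^
fingerprint region, and standardization.

* **Despiking.** A point is a spike when its residual from a running median
  (window `despike_window = 5` points) exceeds `despike_z = 8` MADs of the
  residual distribution; flagged points are linearly interpolated from their
  unflagged neighbours. Runs of flagged points longer than the window are
  considered genuine structure and left alone, so broad real bands can never
  be "repaired" away. A floor of `1e-12 * range` on the MAD keeps perfectly
  smooth noiseless input (where the MAD is 0) from being flagged wholesale.
* **Baseline.** The default is a modified polynomial fit (order 5, up to 100
  refits of `pmin(y, fit)`, stopping when the set of points above the fit
  stabilizes), which needs no solvent measurement. An asymmetric-least-squares
  estimator (`als_lambda = 1e5`, `als_p = 0.01`) and direct subtraction of a
  measured solvent reference are available. Output is *not* clipped at zero:
  small negatives are informative about fit quality. The order-5 polynomial
  carries a structural sag (≈10% of the baseline around 700 cm^-1^ on the
  default synthetic layout) where it must duck under the contiguous
  950–1500 cm^-1^ band mass; the sag is class-independent and cancels after
  phenylalanine normalization, but for *quantitative* baseline recovery the
  ALS mode is the accurate choice (≈2% on the same layout) and is what the
  recovery tests assert at 5%.
* **Normalization.** Intensities are divided by the *maximum* inside
  1004 ± 5 cm^-1^. The window maximum (rather than an integrated area) is
  robust to small calibration shifts; the ±5 cm^-1^ halfwidth tolerates
  instrument-to-instrument shift without escaping the phenylalanine band.
* **Fingerprint crop.** Spectra that do not fully cover \[580, 1800\] cm^-1^
  (closed interval) are dropped; survivors are cropped to exactly that range.
* **Standardization.** "Zero mean and unit variance" is ambiguous between
  rows and columns. The default is per-spectrum (SNV), the chemometric
  convention for removing per-acquisition intensity nuisance; per-wavenumber
  autoscaling is available via `standardize_mode`. Sample standard deviations
  use the n−1 denominator everywhere, matching the t statistics. The
  chemical-imaging branch runs with `standardize_mode = "none"`:
  standardization is a statistics-specific step, and z-scoring each spectrum
  would destroy the band-intensity contrast a map is supposed to display.

The full chain is invariant to any positive rescaling of the raw input
(despike flags depend on residual/MAD ratios, polynomial fitting is linear,
and the phenylalanine division removes the scale).

## Differential statistics

Per wavenumber, a pooled-variance two-sample t statistic (tumor minus normal;
Welch optional) with two-sided p from the t distribution. The FDR is
estimated by label permutation: for threshold c, FDR(c) is the
permutation-mean count of null |t\*| ≥ c divided by the observed count of
|t| ≥ c, and q~j~ is the minimum FDR over all thresholds ≤ |t~j~|, clipped to
\[0, 1\] — monotone non-increasing in |t| by construction, with ties handled
by closed (≥) comparisons for determinism. When the number of distinct label
assignments is ≤ 10,000 they are enumerated exhaustively (and the exhaustive
path is tested bitwise against a brute-force oracle); otherwise B sampled
permutations are used with the observed labeling included among them, which
keeps small-B estimates valid and strictly positive. Permutations shuffle
spectrum labels freely, ignoring the cell/mouse of origin — that is the
minimal reading of the reference protocol; a group-respecting scheme would be
more conservative but is not the default. B and the seed are configuration.

Band summaries report, per band-table window, the fraction of wavenumbers
with q < α and the direction of the mean t; a window is "elevated in tumor"
when at least half its wavenumbers pass with positive direction.

## Penalized logistic classification

The tumor-probability model minimizes the summed negative log-likelihood plus
λ‖β‖² with an unpenalized intercept, by Newton/IRLS with step halving
(convergence at max parameter change < 1e-8, cap 100 iterations; separable
data at λ = 0 simply hit the cap and are flagged unconverged). Columns are
centered and scaled with training statistics that are frozen into the model.
Because the axis (≈1221 wavenumbers) far exceeds the sample count, the fit is
reduced exactly to the training row space by SVD — the optimal coefficient
vector always lies there, and the L2 penalty is rotation-invariant — so every
fit costs O(n³) regardless of axis resolution; the reduced Newton core is
compiled (RcppArmadillo).

λ is chosen from 25 log-spaced values in \[1e-4, 1e4\] by leave-one-out
cross-validated predictive log-likelihood (a smooth criterion that avoids the
ties a 0/1 accuracy criterion produces), ties broken toward the larger λ. One
approximation is made deliberately: within a training fold, columns are
standardized once and the SVD taken once, rather than re-standardizing for
each of the n inner leave-one-out fits. This is the standard fold-level
treatment (cf. how cross-validation is implemented in the mainstream
penalized-regression packages) and keeps the nested search tractable; the
inner refits themselves are exact within the fold's row space.

Out-of-sample performance uses leave-group-out ("leave-cell-out" /
"leave-mouse-out") folds: all spectra from one biological source are held out
together, the penalty search and fit see only the remaining sources, and each
spectrum gets exactly one out-of-fold probability. The call is tumor iff
probability > 0.5, strictly — exactly 0.5 is normal. Borderline spectra are
excluded from both training and testing: the reference protocol excludes them
from prediction, and excluding them from training as well is the conservative
reading (they are neither class). Sensitivity and specificity are reported as
percentages rounded half-up to one decimal.

## PCA and cluster ellipsoids

PCA is the SVD of the column-centered matrix (stable when the axis is much
longer than the spectrum count), with each loading's largest-magnitude
element made positive for sign determinism. Cluster ellipsoids are the mean
and covariance of the first three score coordinates per label; the default
scale draws 1-sd semi-axes (the covariance itself), with a 95% chi-square(3)
coverage scaling available — no coverage level is implied by "covariance structure", and
"covariance structure" reads as the covariance.

## Chemical imaging

A map pixel is the trapezoidal integral of intensity over a closed band
window, endpoints interpolated; single-position bands return the interpolated
intensity. The default window is 1440–1460 cm^-1^ around the CH~2~ lipid
band, since the mapped contrast reflects lipid content; 1050–1100 cm^-1^ is
the documented alternative. Pixels are placed by stage coordinates (row-major,
y outer, origin at the minimum coordinate) on a regular grid inferred from
the modal coordinate step, with 1%-of-step alignment tolerance — never by
input row order. Thresholding is Otsu by default (maximizing between-class
variance over midpoints of consecutive sorted values) or a quantile rule that
calls exactly ⌈qn⌉ brightest pixels positive with ties broken by row-major
index.

## The synthetic world

The generator states, once, the conditions the analysis assumes:

* Bands: one pseudo-Voigt (η = 0.5) component per default band-table row;
  range bands sit at the window midpoint with FWHM spanning the window,
  single bands get FWHM 15 cm^-1^. Unit normal-class amplitude.
* Tumor effect: multiplicative factor 2.0 on every band except the 1004
  phenylalanine reference. The source reports no fold-changes at the
  discriminant bands, so this is a stated free parameter, not a biological
  estimate. Borderline spectra use the geometric mean of the tumor and normal
  amplitudes — the minimal model for a zone "between" the two.
* Designs: 58 tumor spectra over 4 cells (15/15/14/14) vs 40 normal over 2
  astrocytes (20/20); 123 tissue spectra over 6 mice (21, 21, 21, 20, 20, 20,
  each a tumor/normal/borderline mix); a 12 × 22 map at 300 μm step with an
  elliptical tumor region and a borderline ring. The totals are the reference study design's;
  the per-sample splits are the package's stated choices.
* Nuisance: quadratic autofluorescence baseline (coefficients (3.5, 1.5, 2.0)
  in ν/1000, ≈5× peak height at 580 cm^-1^), Gaussian noise sd 0.05,
  Poisson cosmic spikes (rate 0.05/spectrum, 30× noise sd), and lognormal
  per-sample amplitude jitter (sd 0.1 on the log scale) — the grouped
  heterogeneity that makes leave-group-out validation meaningful.
* Tissue attenuation: the tumor−normal amplitude gap is scaled by 0.5 by
  default, emulating the more heterogeneous composition of a tissue spot.

What the generator does *not* emulate: physically calibrated Raman cross
sections, detector response and shot noise, wavelength miscalibration, water
and quartz backgrounds, and spatial correlation between neighbouring map
pixels. A green test therefore establishes that the *algorithms* recover a
known stated structure — not that the instrument-level performance figures
would be reproduced on real tissue. In particular, the reference cell-study
sensitivity/specificity (98.3%/75.0%) and tissue specificity (76.4%) were
computed on undeposited spectra and are not reproducible from data; the
package verifies their confusion-count arithmetic and demonstrates the same
pipeline on its stated synthetic world.

## Numerical choices and degenerate inputs

* Pooled t with zero pooled variance: t = 0 when the mean difference is 0,
  ±Inf otherwise (p = 0); exceedance comparisons are closed (≥) throughout.
* IRLS weights are floored at 1e-10; predicted probabilities are clipped to
  (1e-15, 1−1e-15); leave-one-out log-likelihood contributions clip at 1e-12.
* Zero-variance columns inside the ridge fit get scale 1 (their centered
  values, and hence coefficients, are exactly 0).
* Constant spectra fail per-spectrum standardization with an error naming the
  spectrum; constant maps fail Otsu thresholding.
* All generators are bit-reproducible under a fixed `seed` in the
  configuration.

## Worked example

```{r example, eval = FALSE}
cfg <- generative_config(seed = 1)
cells <- simulate_cell_experiment(cfg = cfg)     # 58 tumor / 40 normal
pp <- preprocess_chain(cells)

res <- permutation_fdr(pp, B = 1000, seed = 1)
summarize_bands(res, default_band_table(), alpha = 0.05)

preds <- leave_group_out_predict(pp)
confusion_metrics(preds)

pc <- pca_spectra(pp, 3)
cluster_ellipsoids(pc)

map <- simulate_map(cfg = cfg)
mpp <- preprocess_chain(map$set, preprocess_config(standardize_mode = "none"))
cm <- build_chemical_map(mpp, band = c(1440, 1460), mask = map$mask)
threshold_map(cm, "otsu")$metrics
```

## Known limitations

* A model trained on cell spectra is not transferable to tissue spectra
  (different optical settings); the package deliberately provides no
  cross-setting prediction path.
* The free-permutation FDR ignores the grouped (per-cell/per-mouse)
  correlation structure and can be anticonservative on strongly grouped data;
  the grouped jitter in the generator is mild by default.
* The inner penalty search standardizes once per training fold (see above);
  with very small folds an exact per-inner-fit standardization could shift
  the selected λ by one grid step.
* Band windows are closed intervals on whatever axis the data carry; with
  very coarse axes a single-position band may be represented by one
  interpolated channel.
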