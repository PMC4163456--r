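# ramandx

Tools for discriminating infiltrative tumor from normal brain with Raman
microspectroscopy. Intraoperative delineation of diffuse glioma is hard
because the tumor has no sharp margin; Raman spectra read out the chemistry —
protein C–C and amide III, lipid C–C and CH₂, nucleic-acid O–P–O bands — that
runs systematically higher in tumor cells and tissue. `ramandx` implements
the complete analysis chain from raw spectra to statistics, classification
and chemical images, plus a synthetic-spectrum generator so that every stage
is testable without instrument data.

## What it computes

* **Preprocessing**: cosmic-ray despiking (running-median / MAD rule),
  baseline subtraction (modified polyfit, asymmetric least squares, or
  solvent-reference subtraction), normalization to the phenylalanine band at
  1004 cm⁻¹, cropping to the 580–1800 cm⁻¹ fingerprint region, and SNV or
  per-wavenumber standardization.
* **Differential band statistics**: per-wavenumber pooled-variance t
  (tumor − normal) with a permutation false discovery rate

  FDR(c) = E₍perm₎ #{k : |t*ₖ| ≥ c} / max(1, #{k : |tₖ| ≥ c}),
  qⱼ = min₍c ≤ |tⱼ|₎ FDR(c),

  exhaustive over all label assignments when feasible, seeded sampling
  otherwise; plus band-window summaries against a packaged assignment table.
* **Classification**: L2-penalized logistic regression minimizing
  −ℓ(β₀, β) + λ‖β‖² (intercept unpenalized) by Newton/IRLS with an exact SVD
  reduction to the training row space, λ chosen by leave-one-out predictive
  log-likelihood inside leave-group-out ("leave-cell-out"/"leave-mouse-out")
  cross-validation; calls are tumor iff probability > 0.5, summarized as
  sensitivity/specificity.
* **Visualization / imaging**: PCA (SVD-based) with per-cluster 3-D
  covariance ellipsoids, and band-intensity chemical maps of gridded
  acquisitions (trapezoidal integration, default 1440–1460 cm⁻¹ lipid CH₂
  band) with Otsu or quantile thresholding against an optional ground-truth
  mask.
* **Synthetic data**: pseudo-Voigt band spectra with autofluorescence
  baseline, Gaussian noise, cosmic spikes and per-sample (cell/mouse)
  amplitude jitter, in the study's acquisition designs: 58 glioma-cell vs 40
  astrocyte spectra, 123 tissue spectra over 6 mice, and a 12 × 22 map at
  300 µm step.

## Worked example

```r
library(ramandx)

cfg  <- generative_config(seed = 7)
cell <- simulate_cell_experiment(cfg = cfg)   # 58 tumor / 40 normal spectra
pp   <- preprocess_chain(cell)

res <- permutation_fdr(pp, B = 200, seed = 1)
res
#> <differential_result> 1221 wavenumbers, 58 tumor vs 40 normal, sampled (201 permutations)
#>   q < 0.05 at 298 wavenumbers

head(summarize_bands(res), 4)
#>     lo   hi              assignment n_wavenumbers frac_significant direction elevated
#> 1  950 1000 C-C (protein, collagen)            51        0.3529412        -1    FALSE
#> 2 1004 1004           phenylalanine             1        1.0000000        -1    FALSE
#> 3 1030 1030     C-H (phenylalanine)             1        0.0000000         1    FALSE
#> 4 1050 1100             C-C (lipid)            51        0.7450980         1     TRUE

preds <- leave_group_out_predict(pp)          # one fold per cell
confusion_metrics(preds)
#> tp=58 fn=0 tn=40 fp=0
#> sensitivity 100.0%  specificity 100.0%
```

The q < 0.05 wavenumbers concentrate in the generator's elevated bands
(lipid 1050–1100 and 1120–1130, protein 1120–1200, CH₂ 1300–1350 and 1450);
the per-spectrum SNV standardization makes some non-elevated regions move in
the opposite direction, which is why the phenylalanine reference shows a
negative direction. The leave-cell-out run is perfect here because the
synthetic effect (×2 on the discriminant bands) is strong relative to the
stated noise; the confusion arithmetic itself is checked against the reference
counts tp=57, fn=1, tn=30, fp=10 → 98.3% / 75.0%.

A command-line interface covers the same pipeline:

```sh
Rscript -e 'ramandx::raman_cli()' simulate --design cell --seed 7 --out /tmp/raw
Rscript -e 'ramandx::raman_cli()' preprocess --in /tmp/raw --out /tmp/pp
Rscript -e 'ramandx::raman_cli()' diff --in /tmp/pp --permutations 1000 --seed 1 --out /tmp/diff.csv
Rscript -e 'ramandx::raman_cli()' classify --in /tmp/pp --out /tmp/clf
```

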