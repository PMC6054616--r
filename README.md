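# fluorostage

Staging liver fibrosis from tissue autofluorescence spectra.

Under 410 nm excitation, liver emits a 440–750 nm autofluorescence spectrum
built from overlapping bands of endogenous fluorophores — NADH (~470 nm),
FAD (~500 nm), lipofuscin-like lipopigments (~590 nm) and porphyrins
(~630 and 670–690 nm) — reshaped by hemoglobin absorption, which carves a
dip near 560 nm (spectral filtering modulation). Fibrosis shifts the FAD
band red (control 501 → mild 505 → moderate 512 nm, back to ~502 nm on
reversal), raises lipopigment and porphyrin emission, blue-shifts the red
porphyrin band from 690 to 670 nm, and lowers tissue hemoglobin.

`fluorostage` implements the complete analysis around those markers, for
spectroscopists and biostatisticians working with (or prototyping against)
label-free fibrosis staging data:

* a **seeded forward simulator** of group-labelled spectra on the standard
  310-point grid (441–750 nm, 1 nm): Gaussian fluorophore bands ×
  Beer–Lambert hemoglobin attenuation with *exact* oxy/deoxy isosbestic
  crossings at 500 and 570 nm, per-animal random effects, additive noise;
* **preprocessing**: resampling and normalization to the 500 ± 10 nm window
  maximum;
* **multi-Gaussian peak decomposition** by bounded Levenberg–Marquardt
  least squares — per band: center, amplitude, σ, FWHM
  (= 2√(2 ln 2) σ), area (= Aσ√(2π)) and the fit chi-square;
* a **ratiometric hemoglobin index** ln(I₅₀₀/I₅₇₀), exactly linear in
  concentration under Beer–Lambert and saturation-independent by the
  isosbestic construction;
* **pairwise PCA–LDA classification** (50/10 train/validation split per
  group, Fisher discriminant with cutoff 0, positive = the more advanced
  lesion), with sensitivity/specificity, threshold-sweep ROC and
  trapezoidal AUC, plus a multiclass discriminant projection with 2-SD
  confidence ellipses and a nearest-centroid confusion matrix;
* **one-way ANOVA** group statistics with 0.05 / 0.005 significance flags.

Everything takes and returns tibbles, composes with the pipe, and is
reproducible from a single seed. Fitted objects have `tidy()`/`glance()`
methods and `autoplot()`/`plot_*()` visualisations.

## Worked example

```r
library(fluorostage)
library(dplyr)

spectra <- generate_dataset(n_per_group = 60, seed = 17) |>
  normalize_spectra()

# five-band decomposition: the FAD center tracks the fibrosis stage
fit_peaks_dataset(spectra) |>
  filter(band == "FAD") |>
  group_by(group) |>
  summarise(center_nm = mean(center_nm), fwhm_nm = mean(fwhm_nm))
#>   group    center_nm fwhm_nm
#> 1 control       502.    40.9
#> 2 mild          505.    41.7
#> 3 moderate      512.    42.1
#> 4 reversal      502.    41.2

# relative total hemoglobin: falls with fibrosis, recovers on reversal
thc_group_summary(spectra)
#>   group        n median   q25   q75   min   max
#> 1 control     60   3.81  3.62  3.96  3.27  4.77
#> 2 mild        60   2.96  2.85  3.03  2.70  3.24
#> 3 moderate    60   2.24  2.19  2.26  2.11  2.37
#> 4 reversal    60   3.68  3.52  3.83  3.17  4.60

# pairwise PCA-LDA staging
cls <- classify_pairs(spectra, seed = 17)
cls$reports |>
  filter(role == "validation") |>
  select(pair, sensitivity, specificity, auc)
#>   pair              sensitivity specificity   auc
#> 1 control-mild              100         100     1
#> 2 mild-moderate             100         100     1
#> 3 reversal-moderate         100         100     1
#> 4 reversal-mild             100         100     1
```

The mean fitted FAD centers reproduce the generator's stage-specific
positions (501/505/512/502 nm) to within a nanometre; the hemoglobin index
medians rank the groups by their preset hemoglobin
(moderate < mild < reversal < control); and on the default synthetic effect
sizes every lesion pair separates completely (on noisier real data the
validation sensitivities/specificities would drop below 100%). `plot_spectra()`,
`plot_thc()`, `plot_roc()` and `plot_discriminant()` draw the corresponding
figures; `run_pipeline(default_config())` chains the whole workflow and
writes every result table plus a JSON run summary.

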