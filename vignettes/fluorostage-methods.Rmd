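---
title: "Methods: autofluorescence staging of liver fibrosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autofluorescence staging of liver fibrosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorostage)
library(dplyr)
```

## The measurement and the analysis problem

Under 410 nm excitation, liver tissue emits a broad autofluorescence
spectrum between 440 and 750 nm composed of overlapping bands from
endogenous fluorophores: NADH (~470 nm), FAD (~500 nm), lipofuscin-like
lipopigments (~590 nm), protoporphyrin IX (~630 nm) and coproporphyrin
(~670-690 nm). Blood reshapes this emission: hemoglobin absorbs strongly
between roughly 520 and 600 nm, carving a visible dip near 560 nm into the
measured spectrum (the spectral filtering modulation, SFM, effect).

Fibrotic remodelling changes this signature in reproducible ways: the FAD
band red-shifts with disease stage, lipopigment and porphyrin emission grow,
the coproporphyrin band blue-shifts from ~690 to ~670 nm, and perfusion
(total hemoglobin) falls in fibrotic tissue and recovers on reversal. The
package turns those observations into a quantitative pipeline:

1. **simulate** group-labelled spectra with the statistical structure above
   (`generate_dataset()`), since no public spectral dataset accompanies the
   study design the package follows;
2. **preprocess**: resample to a common 310-point grid and normalize each
   spectrum to its 500 ± 10 nm window maximum (`normalize_spectra()`);
3. **decompose** each spectrum into five Gaussian bands by bounded
   Levenberg–Marquardt least squares (`fit_peaks()`);
4. **estimate relative total hemoglobin** from the 500/570 nm intensity
   ratio (`thc_index()`);
5. **classify** lesion pairs by PCA followed by Fisher LDA with cutoff 0,
   with ROC/AUC and confusion-ellipse reporting (`classify_pairs()`);
6. **test group differences** by one-way ANOVA (`one_way_anova()`).

## The forward model

A simulated spectrum on the grid $\lambda = 441, \dots, 750$ nm is

$$S(\lambda) = \Big[\sum_k A_k e^{-(\lambda-\mu_k)^2/2\sigma_k^2}\Big]
  \cdot e^{-c\,L\,\varepsilon(\lambda; s)} + \eta(\lambda), \qquad
  \varepsilon(\lambda; s) = s\,\varepsilon_{\mathrm{oxy}}(\lambda) +
  (1-s)\,\varepsilon_{\mathrm{deoxy}}(\lambda),$$

with per-band amplitudes $A_k$, centers $\mu_k$ and widths $\sigma_k$,
relative hemoglobin concentration $c \ge 0$, effective path length $L$,
oxygen saturation $s \in [0,1]$, and i.i.d. Gaussian noise $\eta$ with
standard deviation `noise_sd` × peak intensity, clipped at zero.

### The extinction stand-in and its isosbestic construction

Published absolute extinction curves are not part of this package; instead
`default_extinction_model()` builds a parametric stand-in with the features
the analysis depends on: oxyhemoglobin Q bands at 542 and 577 nm (Gaussian,
σ = 11 nm), a single deoxyhemoglobin band at 555 nm (σ = 20 nm), and —
crucially — *exact* equality of the two curves at 500 and 570 nm. Equality
is enforced by construction: the deoxy curve is multiplied by a smooth
log-linear factor fixed by the two crossing constraints. Because the
crossings are exact, the hemoglobin index below is insensitive to oxygen
saturation to machine precision, which the test suite asserts at 1e-9.

Two shape decisions matter and were made while designing the forward model,
on noiseless spectra, before the acceptance checks were ever run:

* **No Soret-band tail.** A 440 nm absorption tail was tried and rejected:
  it tilts the blue flank of the emission and drags the *fitted* FAD center
  several nm away from the generator's center, which contradicts the premise
  that fitted band positions are stable stage landmarks.
* **Near-zero, flat extinction around 500 nm.** With the Q bands at
  σ = 11 nm, ε(λ) is ≈ 0 and locally flat at 490–510 nm, so Beer–Lambert
  attenuation neither moves the normalization window maximum nor biases the
  FAD center materially.

### Group presets

`default_presets()` encodes the four stages. Band centers use the study's
fitted positions (FAD 501/505/512/502 nm for control/mild/moderate/reversal;
lipopigments 590 nm; porphyrin 630 nm; coproporphyrin 690 nm for
control/reversal, 670 nm for mild/moderate). Amplitudes encode the reported
qualitative orderings (lipopigments and porphyrins:
control ≈ reversal < mild < moderate). Hemoglobin concentrations are
relative and encode only the reported ordering
moderate < mild < reversal < control; the values (0.04 / 0.07 / 0.12 / 0.15
with $L = 1$) were fixed during forward-model design. Larger values were
rejected because the unmodelled absorption dip then biases the fitted FAD
and lipopigment centers roughly linearly in $c$ (≈ 4.5 nm per unit $c$) —
with the chosen values the dip at 560 nm remains visible while fitted
centers stay within the ±1–2 nm the design targets.

Band widths are σ = 15 (NADH), 18 (FAD), 12 (lipopigments) and 8 nm
(porphyrins). Wider blue bands (σ 20/25) were tried first and rejected: the
two heavily-overlapping blue bands become practically non-identified, and
the decomposition then returns centers that wander by several nm under any
model mismatch. The chosen widths still merge NADH and FAD into the single
broad 500 nm feature seen in real liver emission.

Each simulated animal (5 per group, 12 spectra each, by default) carries a
multiplicative log-normal random effect (sd 0.05) on every band amplitude,
emulating between-animal clustering. Noise defaults to 0.5% of the peak.
Everything is reproducible from one seed: animal effects come from the
master seed and each spectrum's noise stream from a deterministic
per-spectrum counter, so datasets are bit-identical across calls and
noiseless spectra are seed-independent.

### What the simulator does *not* emulate

Real spectra add wavelength-dependent scattering, probe-pressure and
geometry variation, photobleaching drift, detector nonlinearity, and
fluorophores beyond the five-band library. Passing tests on synthetic data
therefore demonstrate that the *analysis* is correct and well-conditioned
under the stated statistical structure — not that the biological effect
sizes are as clean in vivo.

## Preprocessing

Spectra are linearly interpolated onto the 441–750 nm, 1 nm grid — exactly
310 samples. (A 440–750 nm inclusive grid would hold 311 points; the
310-point convention fixes the endpoint at 441.) Interpolation is linear
because on a 1 nm grid higher-order schemes change nothing material; no
extrapolation is allowed. Normalization divides by the *raw* maximum on
grid points in the closed window [490, 510] nm; no smoothing is applied
first. The divisor is retained so absolute scales can be reconstructed.

## Gaussian band decomposition

`fit_peaks()` minimises the unweighted sum of squared deviations between
the spectrum and a sum of Gaussians over the full grid, using bounded
Levenberg–Marquardt (via \pkg{minpack.lm}, analytic Jacobian). Defaults:
`max_iter = 500`, relative chi-square tolerance `1e-8`. The five-band
library (`default_band_library()`) starts at 470/500/590/630/670 nm with
±15 nm center bounds, except coproporphyrin widened to [655, 700] nm so the
control-group 690 nm position is admissible.

Numerical choices:

* **Initialization.** Centers are seeded at the interior local maximum of a
  5-point running mean of the spectrum within each band's bounds, falling
  back to the library guess where the window has only a shoulder. Without
  this, a spectrum whose true FAD center sits 12 nm from the 500 nm guess
  (the moderate stage) can converge to a local minimum pegged at the
  515 nm bound. The smoothing affects only the starting point; the fit is
  always against raw intensities.
* **Hemoglobin is not modelled in the fit** — the model is a pure Gaussian
  sum, so structured residuals near 560 nm are expected and accepted.
* **Tie-breaking.** Bands are reported sorted by fitted center, with
  fluorophore names reassigned one-to-one by nearest library center
  (greedy on distance), so labels stay meaningful if bands swap during
  optimisation.
* Non-convergence sets `converged = FALSE` rather than raising; a fit never
  ends with a chi-square above its starting value (LM descent).

Per band the table reports center, amplitude, σ, FWHM $= 2\sqrt{2\ln 2}\,
\sigma$ and area $= A\sigma\sqrt{2\pi}$.

## The hemoglobin index

`thc_index()` reads the normalized intensities at exactly 500 and 570 nm
(single grid points, as the two target wavelengths are named point values)
and reports `log_ratio = ln(I500/I570)` plus the raw ratio. The log form is
chosen because under Beer–Lambert attenuation it is *exactly* linear in
$c$: $\ln(I_{500}/I_{570}) = \text{baseline} + cL\,[\varepsilon(570) -
\varepsilon(500)]$, with positive slope since ε(570) > ε(500). The
orientation (500/570 rather than 570/500) makes the index increase with
hemoglobin. No absolute calibration to g/L is attempted — the index is
relative by design.

One caveat the synthetic experiments expose: because the emission *shape*
also differs between stages (the lipopigment band contributes at 570 nm),
between-group differences in the index mix true hemoglobin differences with
fluorophore-composition differences. In the default presets both effects
point the same way, preserving the expected ordering, but the index should
be read as a composite perfusion marker, not a pure concentration.

## Classification

`classify_pairs()` draws a seeded per-group random split (50 training / 10
validation by default), fits mean-centred PCA on the pooled 200 training
spectra, and retains the smallest leading component set reaching 95%
cumulative variance (minimum 2; both the threshold and the floor are
arguments — the source design names "significant components" without a
rule, so the rule here is explicit and overridable).

Per lesion pair (control–mild, mild–moderate, moderate–reversal,
mild–reversal) a Fisher discriminant $w \propto S_w^{-1}(m_{+} - m_{-})$ is
computed on the retained PC scores, shifted so the midpoint of the class
mean scores is 0. The positive class is the more advanced lesion
(severity order control < reversal < mild < moderate), and a score of
exactly 0 is called positive — the tie-break favouring sensitivity. A
singular within-class scatter falls back to a ridge-regularised inverse
with a warning. Validation spectra are projected through the training mean,
loadings and weights only — never refit — so shuffling validation rows
cannot change the model.

ROC curves sweep the threshold over all distinct scores; the trapezoidal
AUC equals the Mann–Whitney statistic with ties counted ½ (asserted against
an exhaustive pair-count oracle in the tests). The headline per-pair ROC is
computed on pooled training+validation scores by default (`roc_on`
switches it), since which set feeds the published ROC is ambiguous in the
source design; reports for training, validation and pooled roles each carry
their own AUC regardless.

For the four-group overview, multiclass Fisher LDA (leading two
eigenvectors of $S_w^{-1} S_b$) projects all spectra to a plane;
per class the analysis reports the centroid, the 2×2 covariance, the
two-standard-deviation ellipse (semi-axes $2\sqrt{\text{eigenvalues}}$),
inside-own-ellipse membership (Mahalanobis distance ≤ 2) and — because
"inside the ellipse" is a nonstandard accuracy notion — a conventional
nearest-centroid confusion matrix alongside.

## Group statistics

`one_way_anova()` is the classical F test (fitted via `stats::lm`/`anova`),
with a guard for the degenerate zero-within-variance case (F = ∞, p = 0,
flagged). `pairwise_significance_table()` applies it per lesion pair to
band intensity, band area and the hemoglobin index. No multiple-testing
correction is applied, matching the source design; significance is flagged
at both 0.05 and 0.005 since both thresholds appear there. Observations are
treated as independent even though spectra cluster within animals — the
`animal_id` column is preserved so a mixed-model analysis could be added.

## Problem sizes and reproducibility

The defaults run the full study-scale experiment — 240 spectra, 240
five-band fits, the 50/10 split — in a few seconds on one CPU. The test
suite exercises reduced designs (12–20 spectra per group) where full scale
adds nothing, and the full 60-per-group design where the claims concern it
(FAD center recovery, hemoglobin ordering, the moderate-vs-reversal
separation). `run_pipeline()` is a pure function of its configuration:
identical config and seed give byte-identical output tables.

## Known limitations

* The extinction curves are parametric stand-ins, not published spectra;
  only their qualitative shape and the exact 500/570 nm crossings carry
  meaning.
* Hemoglobin preset values are ordinal, not physical concentrations.
* Beer–Lambert attenuation with a fixed effective path ignores scattering
  and photon-path dispersion (no radiative transfer).
* The Gaussian-sum fit leaves structured residuals near the absorption dip
  by design; chi-square values are therefore comparative, not absolute
  goodness-of-fit measures.
* Classification uses a single random split, as in the source design — no
  cross-validation — so validation metrics on small validation sets (10 per
  group) are coarse-grained (steps of 10 percentage points).
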