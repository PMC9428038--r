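---
title: "Methods: phantom FTIR imaging and subtype classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom FTIR imaging and subtype classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlung)
```

## The problem

Mid-infrared microspectroscopy of tissue sections produces, per imaged
area, a hyperspectral cube: a pixel lattice in which every pixel holds an
absorbance spectrum. In the fingerprint region (1800–648 cm⁻¹) those
spectra reflect the local lipid, protein (amide I/II) and nucleic-acid
composition, and the premise of spectral histopathology is that tumour
subtypes leave a *compositional fingerprint* — differences in relative
band intensities rather than shifted or novel peaks. `mirlung` implements
the corresponding supervised analysis end to end: simulate (or read)
per-patient cubes, preprocess, classify every pixel spectrum into SQ,
LUAD or SCLC, and aggregate to patient-level calls.

Because no public FFPE lung-cube dataset accompanies this problem, the
package's first-class citizen is a *phantom generator* whose outputs have
the statistical structure the analysis assumes. All quantitative claims
in the test suite are claims about these phantoms.

## The phantom generator

One patient's cube is built as

absorbance(pixel, ν) = Σ_b f_b · band_b(ν) + baseline(pixel, ν) +
λ · atm(ν) + ε(pixel, ν)

* **Bands.** Each subtype's signature is a list of Gaussian or Lorentzian
  bands; the shipped defaults put all three classes on the same five
  biological positions (≈1740, 1655, 1545, 1240, 1080 cm⁻¹) and separate
  them only by amplitude ratios, the weakest (hence most honest) form of
  class difference. The minimum between-class difference on any single
  band is 0.15 absorbance units. The defaults live in an editable YAML
  file (`inst/extdata/subtype_signatures.yaml`).
* **Patient jitter** f_b: one lognormal factor per band per patient
  (sdlog = `patient_amplitude_sd`, default 0.05). Multiplicative because
  absorbance is non-negative; drawn once per patient so that pixels within
  a patient are exchangeable — the property the patient-level vote
  implicitly assumes.
* **Baseline**: a per-pixel random polynomial (default order 2, coefficient
  sd 0.01 on a wavenumber axis rescaled to [−1, 1]), emulating slowly
  varying drift.
* **Atmospheric contamination**: λ (`atmospheric_level`, default 0 = off)
  times synthetic CO₂ (2360/2340 doublet, 668 cm⁻¹ bend) and H₂O
  (1900–1300 cm⁻¹ comb) line sets. These references are *synthetic*,
  shipped as YAML line lists; no vendor reference spectra are distributed.
* **Pixel noise** ε: i.i.d. Gaussian per pixel-channel
  (`pixel_noise_sd`, default 0.02), emulating detector noise.

Defaults follow the acquisition the package emulates: 4000→648 cm⁻¹ at
8 cm⁻¹ interval (420 channels), 40 × 96 pixels of 6.25 μm (3,840 spectra,
0.15 mm²), 10 patients per subtype. The default noise regime —
band contrast 0.15 vs noise sd 0.02 (7.5×) and 5% patient jitter — was
fixed once, as a plausibly "well-separated" tissue contrast, and is the
regime under which the pipeline is expected to reach perfect patient-level
recovery.

Reproducibility: per-patient seeds are derived from the cohort seed by a
stable integer hash of (seed, subtype, patient index), so regeneration is
bit-identical and enlarging the cohort never changes existing patients.

What the phantom does **not** model: Mie scattering and resonant-Mie
distortion, paraffin residue, tissue morphology (no spatial correlation
between neighbouring pixels), detector drift over acquisition time, and
repeated resections from one patient (every phantom patient is
independent). Consequently, passing tests demonstrate correctness of the
*analysis machinery* under the stated assumptions — not performance on
real FFPE spectra.

## Preprocessing

* **Atmospheric suppression.** For each spectrum s, ordinary least
  squares fits s ≈ offset·1 + Σ_j β_j r_j over the reference set
  {r_j} and subtracts the fitted reference part (the offset is retained).
  This is a documented, reproducible stand-in for the proprietary
  suppression implemented in instrument software; it exactly annihilates
  anything in the references' span and is linear in its input. A
  rank-deficient reference set is rejected by name.
* **PCA denoising.** Spectra are centered by the grand mean spectrum,
  reconstructed from the top k = 20 principal components (SVD of the
  centered matrix), and re-centered. Noise concentrates in low-variance
  components, so the rank-20 reconstruction is noise-reduced without
  broadening peaks — the test suite measures a Gaussian band's FWHM by
  linear interpolation before and after and requires agreement within one
  channel step. Components are reported with a deterministic sign
  convention (largest-magnitude loading positive). No variance scaling is
  applied (spectroscopy convention). Fitting is across the whole table —
  all patients jointly — by default, with a per-patient option; the
  image-level treatment matches how such denoising is applied in
  instrument pipelines, but either choice is defensible and the default is
  flagged here as an assumption.
* **Fingerprint slicing** keeps 1800 ≥ ν ≥ 648 cm⁻¹ inclusive on both
  ends — inclusivity is required to obtain exactly 145 channels on the
  8 cm⁻¹ grid.

Correction precedes denoising; spectra are not normalized before
classification (no evidence either way in the underlying workflow; a
per-channel standardization flag exists on the margin models and is
recorded in the model object).

## Classifiers

All five models train on the *alternating split*: within each patient, in
flatten order, spectra at even 0-based positions are training, odd are
test. The split is per patient so both halves stay balanced per patient,
which the patient vote needs. Balanced halves also make uniform priors
exact.

**Discriminants.** Class means and unbiased covariance estimates
(pooled over classes for the linear variant, per class otherwise); every
covariance is augmented by ridge ε·mean(diag)·I with ε = 10⁻⁶ by default,
purely for numerical definiteness. Decision rules:

* linear: argmax_k xᵀΣ⁻¹μ_k − ½μ_kᵀΣ⁻¹μ_k + ln π_k
* quadratic: argmax_k −½ ln|Σ_k| − ½ d_k²(x) + ln π_k
* Mahalanobis: argmin_k d_k²(x), where d_k² is the squared Mahalanobis
  distance to centroid k in the class's own metric.

The Mahalanobis variant deliberately omits the determinant and prior
terms: that is the classical "distance to centroid" classifier, and the
omission is exactly what lets a class with an inflated covariance absorb
essentially all predictions — the characteristic single-class collapse
this variant is known for, visible in the package as an all-one-column
confusion matrix. Score ties resolve to the lexicographically smaller
label, deterministically.

**Margin models.** One-vs-one linear C-SVC and ν-SVC. Each binary
subproblem is solved to KKT tolerance 10⁻⁷ by libsvm (via `e1071`), and
the hyperplane is extracted explicitly (w = Σ α_i y_i x_i, b = −ρ),
oriented so the pair's first label in (SQ, LUAD, SCLC) order sits on the
positive side. ν feasibility (ν ≤ 2·min(n₊,n₋)/(n₊+n₋)) is checked
before fitting, with the bound cited in the error. Prediction tallies the
K(K−1)/2 votes; vote ties are broken by the larger sum of signed decision
values over the tied labels' machines, then lexicographically. Defaults
C = 1 and ν = 0.5 are explicit assumptions — the commercial software the
workflow originated in discloses neither — as is the one-vs-one scheme
itself (the de-facto convention of C-SVC/ν-SVC implementations).

Correctness is anchored to independent oracles in the test suite: the
discriminant rules against direct per-class formula evaluation (and
`MASS::lda`/`qda` as cross-checks), the C-SVC dual against a brute-force
enumeration of all 3ⁿ KKT states of small problems, the one-vs-one vote
against explicit pairwise tallying, and PCA denoising against an
eigendecomposition-based truncated reconstruction.

## Evaluation

* **Pixel-based**: the 3 × 3 confusion matrix over test spectra in fixed
  (SQ, LUAD, SCLC) order, and one-vs-rest sensitivity, specificity, PPV
  and NPV per class. Empty denominators (0/0) propagate as `NA`, never as
  0 or 100%.
* **Patient-based**: per patient, the fraction of spectra predicted as
  the true subtype; a patient passes cut-off c iff fraction ≥ c (a
  patient exactly at 50% passes). The sweep reports, per model × cut-off
  × subtype, the tally k/10 — non-increasing in the cut-off by
  construction, which the suite asserts exactly.

Patient fractions are computed over **test spectra only** (1,920 of the
3,840 at full geometry) by default. Scoring training spectra would leak
training fit into the headline accuracy; because the alternating split
interleaves spatially adjacent pixels, the two halves are statistically
exchangeable and the test-only fraction estimates the same quantity. The
`vote_pool = "all"` switch restores the all-spectra variant for
comparison.

## Numerical choices and degenerate inputs

* Grid construction rejects a step that does not divide the span, naming
  the remainder; grids are reconstructed from channel names when tables
  travel through CSV.
* `pca_denoise` with k at or above the rank of the centered matrix is the
  identity (to numerical precision); rank is determined by a singular
  value threshold of max(dim)·σ₁·eps.
* Discriminant fitting refuses a singular covariance at ridge 0 rather
  than silently pseudo-inverting.
* Ties (discriminant scores, SVM votes) always resolve deterministically,
  so refitting on identical input reproduces identical predictions.
* Long-CSV interchange writes absorbances with 17 significant digits and
  parses them through strtod, making write-then-read bit-exact; the ENVI
  writer stores 32-bit floats (round trip exact to ~10⁻⁷ relative).

## Problem sizes

The suite and the acceptance script run on a *reduced* cohort — 30
patients of 10 × 24-pixel cubes on the full 420-channel grid, sliced to
145 fingerprint channels (7,200 spectra, 3,600 training) — which exercises
every stage at full spectral dimensionality while keeping the five-model
experiment in the seconds range. Single tests use the full 40 × 96
geometry where a printed constant depends on it (3,840 spectra, 0.15 mm²,
1,920/1,920 split). The oracle-backed classifier checks run on ≤ 50-point
instances, where brute force is exact and fast.

## Known limitations

* Phantom realism is deliberately minimal (see above); in particular the
  absence of pixel-to-pixel spatial correlation makes the patient vote
  easier than on real tissue, where whole regions fail together.
* Absorbance units are arbitrary: the source workflow never states a
  dynamic range, so amplitudes are fixed by convention, and only relative
  contrasts (band differences vs noise sd) are meaningful.
* The atmospheric suppressor is a least-squares reference fit, not a
  reimplementation of any vendor algorithm.
* Patient-based accuracy on phantoms should not be read as a forecast of
  clinical accuracy; it verifies the pipeline's behaviour under its own
  assumptions.
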