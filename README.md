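# mirlung

Label-free mid-infrared (FTIR) hyperspectral imaging can separate the three
major lung cancer subtypes — squamous cell carcinoma (SQ), adenocarcinoma
(LUAD) and small-cell carcinoma (SCLC) — from formalin-fixed
paraffin-embedded (FFPE) tissue sections, without stains or
immunohistochemistry. `mirlung` implements that analysis as a tested,
reusable R pipeline:

* **Phantom cohorts** — synthetic per-patient hyperspectral cubes with the
  statistical structure the analysis assumes (absorbance spectra on a
  4000–648 cm⁻¹ axis at 8 cm⁻¹ data interval; 40 × 96 pixels of
  6.25 μm × 6.25 μm, i.e. 3,840 spectra over 0.15 mm² per patient; 10
  patients per subtype). Subtypes differ in the relative amplitudes of five
  shared biological bands (lipid ester ~1740, amide I ~1655, amide II
  ~1545, nucleic-acid/phosphate ~1240 and ~1080 cm⁻¹); patients carry
  multiplicative amplitude jitter, pixels carry additive noise, baseline
  drift and optional atmospheric CO₂/H₂O contamination.
* **Preprocessing** — least-squares suppression of atmospheric CO₂/H₂O
  reference spectra, noise reduction by 20-factor PCA reconstruction
  (which, unlike smoothing, does not broaden peaks), and restriction to
  the 145 fingerprint wavenumbers (1800–648 cm⁻¹).
* **Five classifiers** — linear, quadratic and Mahalanobis-distance
  discriminant analysis, and linear C-SVC / ν-SVC support vector machines
  (one-vs-one voting), trained on every second spectrum.
* **Two evaluation regimes** — pixel-based confusion-matrix metrics
  (sensitivity, specificity, PPV, NPV per subtype) and patient-based
  cut-off voting: a patient is called correct at cut-off *c* when at least
  a fraction *c* of their spectra are predicted as the true subtype, for
  *c* ∈ {50, 60, 70, 80, 90, 95}%.

Real data can enter the same pipeline through a long-format CSV or an
ENVI-style cube reader.

## The models

With class means μ_k, pooled covariance Σ (linear) or per-class Σ_k
(quadratic, Mahalanobis) and uniform priors π_k, a spectrum x is assigned
by:

* linear: argmax_k xᵀΣ⁻¹μ_k − ½μ_kᵀΣ⁻¹μ_k + ln π_k
* quadratic: argmax_k −½ ln|Σ_k| − ½(x−μ_k)ᵀΣ_k⁻¹(x−μ_k) + ln π_k
* Mahalanobis: argmin_k (x−μ_k)ᵀΣ_k⁻¹(x−μ_k) (no determinant, no prior)

The margin classifiers solve the standard linear-kernel soft-margin duals
(C-SVC with box constraint 0 ≤ α_i ≤ C; ν-SVC with the ν
parameterization), one binary machine per subtype pair, each machine's
hyperplane extracted explicitly as (w, b); multi-class prediction is by
vote, ties broken by summed signed decision values.

## Worked example

```r
library(mirlung)

cfg <- run_config(
  phantom = phantom_config(image_width_px = 24, image_height_px = 10,
                           atmospheric_level = 0.05, seed = 101),
  models = c("svm_c", "lda_quadratic")
)
ex <- run_full_experiment(cfg)
glance(ex)
#> # A tibble: 2 × 3
#>   model         pixel_accuracy patient_accuracy_50
#>   <chr>                  <dbl>               <dbl>
#> 1 svm_c                      1                   1
#> 2 lda_quadratic              1                   1

dplyr::filter(ex$sweep, cutoff == 0.5)
#> # A tibble: 6 × 6
#>   model         subtype cutoff n_correct n_total accuracy
#>   <chr>         <fct>    <dbl>     <int>   <int>    <dbl>
#> 1 lda_quadratic SQ         0.5        10      10        1
#> 2 lda_quadratic LUAD       0.5        10      10        1
#> 3 lda_quadratic SCLC       0.5        10      10        1
#> 4 svm_c         SQ         0.5        10      10        1
#> 5 svm_c         LUAD       0.5        10      10        1
#> 6 svm_c         SCLC       0.5        10      10        1
```

At the default separation (minimum between-class band contrast 0.15
absorbance units against pixel noise of sd 0.02) every patient of the
reduced 24 × 10-pixel cohort is recovered: all 10/10 per subtype at the
50% cut-off, and pixel-level accuracy 1. Raising the pixel noise to 0.6
(4× the band contrast) degrades the same pipeline visibly:

```r
cfg_noisy <- run_config(
  phantom = phantom_config(image_width_px = 24, image_height_px = 10,
                           pixel_noise_sd = 0.6, seed = 101),
  models = "svm_c"
)
dplyr::filter(run_full_experiment(cfg_noisy)$metrics, model == "svm_c")
#> # A tibble: 3 × 6
#>   model class sensitivity specificity   ppv   npv
#>   <chr> <chr>       <dbl>       <dbl> <dbl> <dbl>
#> 1 svm_c SQ          0.586       0.743 0.533 0.782
#> 2 svm_c LUAD        0.356       0.786 0.454 0.709
#> 3 svm_c SCLC        0.608       0.746 0.545 0.792
```

Per-subtype sensitivities drop toward chance and the patient vote starts
missing patients at higher cut-offs — the qualitative pattern the
cut-off sweep is designed to expose. `autoplot(ex)` draws accuracy
against cut-off per model and subtype; `plot_mean_spectra(table)` shows
the class mean spectra.

A shell interface wraps the same stages
(`generate`, `preprocess`, `split`, `train`, `predict`, `evaluate`,
`sweep`, `run-all`):

```sh
Rscript inst/scripts/mirlung run-all --config cfg.yaml --out out/
```

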