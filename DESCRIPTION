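Package: mirlung
Title: Mid-Infrared Hyperspectral Classification of Lung Cancer Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and supervised classification pipeline for label-free
    mid-infrared (FTIR) hyperspectral imaging of formalin-fixed
    paraffin-embedded lung tumour tissue. Generates phantom per-patient
    spectral cubes with Gaussian/Lorentzian band models, patient-level
    amplitude jitter, baseline drift and atmospheric CO2/H2O contamination;
    preprocesses spectra by least-squares atmospheric suppression, 20-factor
    principal-component noise reduction and fingerprint-region
    (1800-648 cm-1) selection; classifies pixel spectra into squamous cell
    carcinoma, adenocarcinoma and small-cell carcinoma with linear, quadratic
    and Mahalanobis discriminant models and linear C-SVC / nu-SVC support
    vector machines; and evaluates both pixel-based confusion-matrix metrics
    and patient-based majority-vote accuracy across classification cut-offs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
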