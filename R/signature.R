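#' Absorption band
#'
#' One vibrational band used to synthesize phantom tissue spectra, with a
#' Gaussian or Lorentzian line shape. The band evaluates to `amplitude` at
#' its center and to `amplitude / 2` at `center_cm1 +/- fwhm_cm1 / 2`.
#'
#' @param center_cm1 Band center, cm^-1.
#' @param fwhm_cm1 Full width at half maximum, cm^-1, positive.
#' @param amplitude Peak absorbance (arbitrary absorbance units), non-negative.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return A one-row tibble describing the band.
#' @export
ir_band <- function(center_cm1, fwhm_cm1, amplitude,
                    shape = c("gaussian", "lorentzian")) {
  shape <- rlang::arg_match(shape)
  if (!is.numeric(fwhm_cm1) || fwhm_cm1 <= 0) {
    rlang::abort("`fwhm_cm1` must be positive.")
  }
  if (!is.numeric(amplitude) || amplitude < 0) {
    rlang::abort("`amplitude` must be non-negative.")
  }
  tibble::tibble(
    center_cm1 = as.numeric(center_cm1),
    fwhm_cm1 = as.numeric(fwhm_cm1),
    amplitude = as.numeric(amplitude),
    shape = shape
  )
}

#' Class signature: the band set of one tumour subtype
#'
#' A signature ties a subtype label (SQ, LUAD or SCLC) to a set of absorption
#' bands. The default signatures share band *positions* (lipid ester ~1740,
#' amide I ~1655, amide II ~1545, nucleic-acid/phosphate ~1240 and ~1080
#' cm^-1) and differ only in relative band amplitudes, so subtypes are
#' distinguished by a compositional fingerprint, not by shifted peaks.
#'
#' @param subtype Subtype label, one of `"SQ"`, `"LUAD"`, `"SCLC"`.
#' @param bands A tibble of bands as produced by [ir_band()] (rows may be
#'   bound together), with at least one row.
#' @return An object of class `ir_signature`.
#' @seealso [default_signatures()], [eval_signature()]
#' @export
ir_signature <- function(subtype, bands) {
  subtype <- match.arg(subtype, subtype_levels())
  bands <- tibble::as_tibble(bands)
  needed <- c("center_cm1", "fwhm_cm1", "amplitude", "shape")
  if (!all(needed %in% names(bands)) || nrow(bands) < 1L) {
    rlang::abort(
      "`bands` needs at least one row with columns center_cm1, fwhm_cm1, amplitude, shape."
    )
  }
  if (any(bands$fwhm_cm1 <= 0) || any(bands$amplitude < 0)) {
    rlang::abort("Band widths must be positive and amplitudes non-negative.")
  }
  if (!all(bands$shape %in% c("gaussian", "lorentzian"))) {
    rlang::abort("Band shape must be 'gaussian' or 'lorentzian'.")
  }
  structure(list(subtype = subtype, bands = bands), class = "ir_signature")
}

#' @export
print.ir_signature <- function(x, ...) {
  cat(sprintf("<ir_signature> %s, %d bands\n", x$subtype, nrow(x$bands)))
  print(x$bands)
  invisible(x)
}

#' The three histological subtype labels, in fixed reporting order
#'
#' @return `c("SQ", "LUAD", "SCLC")` — squamous cell carcinoma,
#'   adenocarcinoma, small-cell carcinoma.
#' @export
subtype_levels <- function() c("SQ", "LUAD", "SCLC")

# Evaluate a band table at wavenumbers `wn`, with per-band amplitude scale
# factors (a vector recycled over bands). Returns length(wn) vector.
eval_bands <- function(bands, wn, scale = 1) {
  scale <- rep_len(scale, nrow(bands))
  out <- numeric(length(wn))
  for (i in seq_len(nrow(bands))) {
    a <- bands$amplitude[i] * scale[i]
    c0 <- bands$center_cm1[i]
    w <- bands$fwhm_cm1[i]
    out <- out + switch(bands$shape[i],
      gaussian = a * exp(-4 * log(2) * ((wn - c0) / w)^2),
      lorentzian = a * (w / 2)^2 / ((wn - c0)^2 + (w / 2)^2)
    )
  }
  out
}

#' Evaluate a class signature on a wavenumber grid
#'
#' Sums the band profiles of the signature at each grid wavenumber.
#' Gaussian bands contribute
#' `amplitude * exp(-4 ln 2 ((nu - center) / fwhm)^2)`; Lorentzian bands
#' `amplitude * (fwhm/2)^2 / ((nu - center)^2 + (fwhm/2)^2)`.
#'
#' @param signature An [ir_signature()].
#' @param grid A [wn_grid()].
#' @return Numeric absorbance vector of length `grid$n_channels`.
#' @export
eval_signature <- function(signature, grid) {
  stopifnot(inherits(signature, "ir_signature"), inherits(grid, "wn_grid"))
  eval_bands(signature$bands, wn_values(grid))
}

#' Default subtype signatures
#'
#' Loads the shipped band sets for SQ, LUAD and SCLC from an editable YAML
#' file. All three classes use the same five biological band positions and
#' differ in amplitude ratios (e.g. SCLC, a small-cell tumour with high
#' nuclear density, carries the strongest nucleic-acid/phosphate bands).
#'
#' @param path YAML file of band lists; defaults to the file shipped with
#'   the package.
#' @return Named list of three [ir_signature()] objects (SQ, LUAD, SCLC).
#' @export
default_signatures <- function(path = system.file("extdata", "subtype_signatures.yaml",
                                                  package = "mirlung")) {
  spec <- yaml::read_yaml(path)
  missing <- setdiff(subtype_levels(), names(spec))
  if (length(missing) > 0) {
    rlang::abort(paste0("Signature file lacks subtype(s): ",
                        paste(missing, collapse = ", ")))
  }
  purrr::imap(spec[subtype_levels()], function(bands, subtype) {
    ir_signature(subtype, purrr::map_dfr(bands, tibble::as_tibble))
  })
}
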