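#' Phantom cohort configuration
#'
#' Bundles everything needed to generate a synthetic cohort of per-patient
#' hyperspectral cubes emulating transflection FTIR imaging of FFPE lung
#' tumour sections: the spectral grid, image geometry, the three subtype
#' signatures, and the stochastic components (per-patient amplitude jitter,
#' per-pixel noise, baseline drift, atmospheric contamination).
#'
#' Defaults mirror the acquisition this package emulates: a 4000–648 cm^-1
#' axis at 8 cm^-1 data interval (420 channels), 40 x 96 pixel images at
#' 6.25 um pixel size (3,840 spectra over 0.15 mm^2), and 10 patients per
#' subtype (30 cubes).
#'
#' @param grid Spectral axis, a [wn_grid()].
#' @param image_width_px,image_height_px Image geometry in pixels.
#' @param pixel_size_um Pixel edge length, micrometres.
#' @param patients_per_class Patients simulated per subtype.
#' @param signatures Named list of three [ir_signature()]s with distinct
#'   subtypes (default [default_signatures()]).
#' @param patient_amplitude_sd Relative (lognormal sdlog) multiplicative
#'   jitter applied to each band amplitude once per patient; models
#'   between-patient compositional variation.
#' @param pixel_noise_sd Additive i.i.d. Gaussian noise per pixel-channel
#'   (absorbance units); models detector noise.
#' @param baseline_order Polynomial order of the per-pixel baseline drift.
#' @param baseline_sd Standard deviation of each baseline polynomial
#'   coefficient (absorbance units, on a wavenumber axis rescaled to [-1, 1]).
#' @param atmospheric_level Scale of the added CO2/H2O reference spectrum;
#'   0 disables contamination.
#' @param seed Integer master seed; all per-patient seeds derive from it.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid = wn_grid(4000, 648, 8),
                           image_width_px = 96,
                           image_height_px = 40,
                           pixel_size_um = 6.25,
                           patients_per_class = 10,
                           signatures = default_signatures(),
                           patient_amplitude_sd = 0.05,
                           pixel_noise_sd = 0.02,
                           baseline_order = 2,
                           baseline_sd = 0.01,
                           atmospheric_level = 0,
                           seed = 1L) {
  stopifnot(inherits(grid, "wn_grid"))
  if (patients_per_class < 1) rlang::abort("`patients_per_class` must be >= 1.")
  sds <- c(patient_amplitude_sd, pixel_noise_sd, baseline_sd, atmospheric_level)
  if (any(sds < 0)) rlang::abort("Stochastic scale parameters must be >= 0.")
  if (image_width_px < 1 || image_height_px < 1) {
    rlang::abort("Image geometry must be at least 1 x 1 pixels.")
  }
  if (length(signatures) != 3L ||
      !all(purrr::map_lgl(signatures, inherits, "ir_signature"))) {
    rlang::abort("`signatures` must be a list of exactly three ir_signature objects.")
  }
  subtypes <- purrr::map_chr(signatures, "subtype")
  if (anyDuplicated(subtypes) || !setequal(subtypes, subtype_levels())) {
    rlang::abort("Signatures must cover SQ, LUAD and SCLC exactly once each.")
  }
  names(signatures) <- subtypes
  centers <- unlist(purrr::map(signatures, ~ .x$bands$center_cm1))
  if (any(centers > grid$start_cm1 | centers < grid$end_cm1)) {
    rlang::abort("All signature band centers must lie within the grid span.")
  }
  structure(
    list(
      grid = grid,
      image_width_px = as.integer(image_width_px),
      image_height_px = as.integer(image_height_px),
      pixel_size_um = pixel_size_um,
      patients_per_class = as.integer(patients_per_class),
      signatures = signatures[subtype_levels()],
      patient_amplitude_sd = patient_amplitude_sd,
      pixel_noise_sd = pixel_noise_sd,
      baseline_order = as.integer(baseline_order),
      baseline_sd = baseline_sd,
      atmospheric_level = atmospheric_level,
      seed = as.integer(seed)
    ),
    class = "phantom_config"
  )
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<phantom_config> %d x %d px @ %g um, grid %s (%d ch), ",
      "%d patients/class, jitter sd %g, noise sd %g, baseline o%d sd %g, ",
      "atmospheric %g, seed %d\n"
    ),
    x$image_height_px, x$image_width_px, x$pixel_size_um, format(x$grid),
    x$grid$n_channels, x$patients_per_class, x$patient_amplitude_sd,
    x$pixel_noise_sd, x$baseline_order, x$baseline_sd, x$atmospheric_level,
    x$seed
  ))
  invisible(x)
}

# Stable 31-bit integer hash of the master seed plus patient identity.
# Adding a patient (higher index) never perturbs existing patients' seeds.
patient_seed_hash <- function(seed, subtype, index) {
  key <- sprintf("%d|%s|%d", as.integer(seed), subtype, as.integer(index))
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

#' Generate one patient's hyperspectral cube
#'
#' Builds the pixel lattice for a single phantom patient. Every pixel
#' spectrum is the patient-jittered class signature (each band amplitude
#' multiplied by one lognormal factor drawn per patient) plus a per-pixel
#' random baseline polynomial, plus `atmospheric_level` times the combined
#' CO2/H2O reference, plus i.i.d. Gaussian noise per pixel-channel.
#' Deterministic given `patient_seed`.
#'
#' @param config A [phantom_config()].
#' @param subtype One of the config's signature subtypes.
#' @param patient_id Unique patient identifier string.
#' @param patient_seed Integer RNG seed for this patient.
#' @return An object of class `spectral_cube`: fields `patient_id`,
#'   `subtype`, `grid`, `absorbance` (height x width x channels array) and
#'   `pixel_size_um`.
#' @export
generate_patient_cube <- function(config, subtype, patient_id, patient_seed) {
  stopifnot(inherits(config, "phantom_config"))
  if (!subtype %in% names(config$signatures)) {
    rlang::abort(sprintf("Unknown subtype '%s'; config has %s.", subtype,
                         paste(names(config$signatures), collapse = ", ")))
  }
  h <- config$image_height_px
  w <- config$image_width_px
  npx <- h * w
  wn <- wn_values(config$grid)
  nch <- length(wn)
  bands <- config$signatures[[subtype]]$bands

  atm <- if (config$atmospheric_level > 0) {
    refs <- atmospheric_references(config$grid)
    config$atmospheric_level * colSums(refs$references)
  } else {
    numeric(nch)
  }

  withr::with_seed(as.integer(patient_seed), {
    fac <- if (config$patient_amplitude_sd > 0) {
      exp(stats::rnorm(nrow(bands), 0, config$patient_amplitude_sd))
    } else {
      rep(1, nrow(bands))
    }
    base_spec <- eval_bands(bands, wn, scale = fac) + atm

    # pixel spectra in row-major pixel order: p = col + (row-1)*w
    m <- matrix(base_spec, nrow = npx, ncol = nch, byrow = TRUE)
    if (config$baseline_sd > 0) {
      t01 <- 2 * (wn - config$grid$end_cm1) /
        (config$grid$start_cm1 - config$grid$end_cm1) - 1
      powers <- outer(t01, 0:config$baseline_order, `^`) # nch x (o+1)
      coefs <- matrix(stats::rnorm(npx * (config$baseline_order + 1),
                                   0, config$baseline_sd),
                      nrow = npx)
      m <- m + coefs %*% t(powers)
    }
    if (config$pixel_noise_sd > 0) {
      m <- m + matrix(stats::rnorm(npx * nch, 0, config$pixel_noise_sd),
                      nrow = npx)
    }
  })

  # reshape row-major pixel matrix into a (row, col, channel) array
  a <- array(m, dim = c(w, h, nch))
  a <- aperm(a, c(2, 1, 3))
  structure(
    list(
      patient_id = patient_id,
      subtype = subtype,
      grid = config$grid,
      absorbance = a,
      pixel_size_um = config$pixel_size_um
    ),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$absorbance)
  cat(sprintf(
    "<spectral_cube> %s (%s): %d x %d px, %d channels, %.2f mm^2\n",
    x$patient_id, x$subtype, d[1], d[2], d[3], cube_area_mm2(x)
  ))
  invisible(x)
}

#' Imaged area of a cube in mm^2
#' @param cube A `spectral_cube`.
#' @return Area covered by the pixel lattice, mm^2.
#' @export
cube_area_mm2 <- function(cube) {
  d <- dim(cube$absorbance)
  d[1] * d[2] * (cube$pixel_size_um / 1000)^2
}

#' Generate a full phantom cohort
#'
#' Generates `patients_per_class` cubes for each of SQ, LUAD and SCLC.
#' Per-patient seeds are derived from `config$seed` by a stable integer
#' hash of (seed, subtype, index), so regeneration with the same config is
#' bit-identical and adding patients never changes existing ones.
#'
#' @param config A [phantom_config()].
#' @return An object of class `patient_cohort`: list with `cubes` (list of
#'   [generate_patient_cube()] results, 3 x patients_per_class of them) and
#'   `config`.
#' @examples
#' cfg <- phantom_config(image_width_px = 6, image_height_px = 4,
#'                       patients_per_class = 1, seed = 7)
#' cohort <- generate_cohort(cfg)
#' length(cohort$cubes)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  cubes <- purrr::flatten(purrr::map(subtype_levels(), function(st) {
    purrr::map(seq_len(config$patients_per_class), function(i) {
      generate_patient_cube(
        config, st,
        patient_id = sprintf("%s_%02d", st, i),
        patient_seed = patient_seed_hash(config$seed, st, i)
      )
    })
  }))
  structure(list(cubes = cubes, config = config), class = "patient_cohort")
}

#' @export
print.patient_cohort <- function(x, ...) {
  tab <- table(purrr::map_chr(x$cubes, "subtype"))
  cat(sprintf("<patient_cohort> %d cubes (%s)\n", length(x$cubes),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Tidy a spectral cube into a long tibble
#'
#' @param x A `spectral_cube`.
#' @param ... Unused.
#' @return Long tibble with columns patient_id, subtype, row, col (0-based),
#'   wavenumber_cm1, absorbance; pixels in row-major order, channels
#'   descending.
#' @export
tidy.spectral_cube <- function(x, ...) {
  d <- dim(x$absorbance)
  wn <- wn_values(x$grid)
  px <- tidyr::expand_grid(row = 0:(d[1] - 1), col = 0:(d[2] - 1))
  tibble::tibble(
    patient_id = x$patient_id,
    subtype = x$subtype,
    row = rep(px$row, each = d[3]),
    col = rep(px$col, each = d[3]),
    wavenumber_cm1 = rep(wn, times = d[1] * d[2]),
    absorbance = as.vector(aperm(x$absorbance, c(3, 2, 1)))
  )
}
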