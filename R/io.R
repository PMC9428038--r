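#' Write / read a spectral cube as long-format CSV
#'
#' The canonical interchange format: one row per (pixel, channel) with
#' columns `patient_id, subtype, row, col, wavenumber_cm1, absorbance`
#' (pixel coordinates 0-based, channels descending). Absorbances are
#' written with 17 significant digits, so a write-then-read round trip is
#' bit-exact.
#'
#' @param cube A `spectral_cube`.
#' @param path Output CSV path.
#' @param pixel_size_um Pixel size to assume when reading (the CSV does not
#'   carry it); default 6.25.
#' @return `write_cube_csv()` returns `path` invisibly; `read_cube_csv()`
#'   returns a `spectral_cube`.
#' @export
write_cube_csv <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  df <- tidy(cube)
  # 17 significant digits: the shortest precision that round-trips doubles
  df$absorbance <- sprintf("%.17g", df$absorbance)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_cube_csv
#' @export
read_cube_csv <- function(path, pixel_size_um = 6.25) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(absorbance = "c"))
  # parse via strtod for correctly rounded doubles (bit-exact round trip)
  if (is.character(df$absorbance)) df$absorbance <- as.numeric(df$absorbance)
  needed <- c("patient_id", "subtype", "row", "col", "wavenumber_cm1", "absorbance")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    rlang::abort(paste0("Cube CSV is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  wn <- unique(df$wavenumber_cm1)
  grid <- grid_from_values(wn)
  h <- max(df$row) + 1
  w <- max(df$col) + 1
  if (nrow(df) != h * w * grid$n_channels) {
    rlang::abort(sprintf(
      "Cube CSV has %d rows; expected %d x %d pixels x %d channels = %d.",
      nrow(df), h, w, grid$n_channels, h * w * grid$n_channels
    ))
  }
  # rows are pixel row-major, channel-fastest (the tidy() order)
  a <- array(df$absorbance, dim = c(grid$n_channels, w, h))
  a <- aperm(a, c(3, 2, 1))
  structure(
    list(
      patient_id = df$patient_id[1],
      subtype = df$subtype[1],
      grid = grid,
      absorbance = a,
      pixel_size_um = pixel_size_um
    ),
    class = "spectral_cube"
  )
}

#' Write / read a spectral cube in ENVI format
#'
#' A minimal ENVI-style pair: a text header (`<path>.hdr`) and a flat
#' band-sequential binary (`<path>.dat`) of little-endian 32-bit floats.
#' The header carries geometry, the wavelength list and, as extension keys,
#' patient id, subtype and pixel size. Because storage is 32-bit, a
#' round trip is exact only to single precision (~1e-7 relative).
#'
#' @param cube A `spectral_cube`.
#' @param path Base path without extension.
#' @return `write_cube_envi()` returns `path` invisibly; `read_cube_envi()`
#'   a `spectral_cube`.
#' @export
write_cube_envi <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$absorbance)
  hdr <- c(
    "ENVI",
    "description = {mirlung spectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = cm-1",
    sprintf("wavelength = {%s}", paste(format_wn(wn_values(cube$grid)), collapse = ", ")),
    sprintf("patient id = %s", cube$patient_id),
    sprintf("subtype = %s", cube$subtype),
    sprintf("pixel size um = %g", cube$pixel_size_um)
  )
  writeLines(hdr, paste0(path, ".hdr"))
  # BSQ: band by band, each band lines x samples in row-major line order
  v <- as.vector(aperm(cube$absorbance, c(2, 1, 3)))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_cube_envi
#' @export
read_cube_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) {
    rlang::abort(sprintf("ENVI header not found: %s", hdr_path))
  }
  lines <- readLines(hdr_path)
  get <- function(key, required = TRUE) {
    hit <- grep(paste0("^", key, " *="), lines, value = TRUE)
    if (length(hit) == 0) {
      if (required) rlang::abort(sprintf("ENVI header lacks '%s' (%s).", key, hdr_path))
      return(NULL)
    }
    sub(paste0("^", key, " *= *"), "", hit[1])
  }
  samples <- as.integer(get("samples"))
  nlines <- as.integer(get("lines"))
  bands <- as.integer(get("bands"))
  if (get("interleave") != "bsq" || as.integer(get("data type")) != 4L) {
    rlang::abort("Only BSQ float32 ENVI cubes are supported.")
  }
  wl_raw <- get("wavelength")
  wn <- as.numeric(strsplit(gsub("[{}]", "", wl_raw), ",")[[1]])
  if (anyNA(wn) || length(wn) != bands) {
    rlang::abort("Malformed ENVI wavelength list.")
  }
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  v <- readBin(con, what = numeric(), n = samples * nlines * bands,
               size = 4, endian = "little")
  if (length(v) != samples * nlines * bands) {
    rlang::abort("ENVI binary is shorter than the header promises.")
  }
  a <- aperm(array(v, dim = c(samples, nlines, bands)), c(2, 1, 3))
  structure(
    list(
      patient_id = get("patient id"),
      subtype = get("subtype"),
      grid = grid_from_values(wn),
      absorbance = a,
      pixel_size_um = as.numeric(get("pixel size um"))
    ),
    class = "spectral_cube"
  )
}

#' Write / read a spectra table as wide CSV
#'
#' Metadata columns plus one `wn_<wavenumber>` column per channel; used by
#' the command-line stages to pass tables between steps.
#'
#' @param table A spectra table.
#' @param path CSV path.
#' @return `write_spectra_csv()` returns `path` invisibly;
#'   `read_spectra_csv()` the reconstructed table.
#' @export
write_spectra_csv <- function(table, path) {
  m <- spc_matrix(table)
  wide <- dplyr::select(table, -"absorbance")
  wide <- dplyr::select(wide, dplyr::any_of(c("patient_id", "subtype", "row", "col", "role")))
  spec_cols <- tibble::as_tibble(as.data.frame(m))
  names(spec_cols) <- paste0("wn_", colnames(m))
  readr::write_csv(dplyr::bind_cols(wide, spec_cols), path)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  spec_cols <- grep("^wn_", names(df), value = TRUE)
  if (length(spec_cols) < 2) {
    rlang::abort("Spectra CSV has no wn_<wavenumber> channel columns.")
  }
  wn <- as.numeric(sub("^wn_", "", spec_cols))
  m <- as.matrix(df[spec_cols])
  grid <- grid_from_values(wn)
  meta <- df[setdiff(names(df), spec_cols)]
  spectra_table(meta, m, grid)
}

#' Serialize a fitted model to JSON
#'
#' Writes a documented JSON container holding the model family, labels,
#' hyperparameters, channel set and fitted state (means/covariances for
#' discriminants; per-machine weights, bias and dual coefficients for
#' margin models), at full numeric precision.
#'
#' @param model A `mir_lda` or `mir_svm`.
#' @param path Output JSON path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   reconstructed model.
#' @export
write_model <- function(model, path) {
  obj <- if (inherits(model, "mir_lda")) {
    list(
      family = "mir_lda", variant = model$variant, labels = model$labels,
      wavenumbers = model$wavenumbers, means = model$means,
      cov = model$cov, covs = model$covs, priors = as.list(model$priors),
      ridge_eps = model$ridge_eps, n_train = model$n_train
    )
  } else if (inherits(model, "mir_svm")) {
    list(
      family = "mir_svm", formulation = model$formulation,
      cost = model$cost, nu = model$nu, labels = model$labels,
      wavenumbers = model$wavenumbers,
      center = model$center, scale_sd = model$scale_sd,
      machines = model$machines
    )
  } else {
    rlang::abort("`model` must be a mir_lda or mir_svm.")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (identical(obj$family, "mir_lda")) {
    covs <- obj$covs
    if (!is.null(covs)) covs <- purrr::map(covs, as.matrix)
    structure(
      list(
        variant = obj$variant, labels = obj$labels,
        means = matrix(as.matrix(obj$means), nrow = length(obj$labels)),
        cov = if (is.null(obj$cov)) NULL else as.matrix(obj$cov),
        covs = covs,
        priors = unlist(obj$priors),
        ridge_eps = obj$ridge_eps,
        wavenumbers = obj$wavenumbers,
        n_train = obj$n_train
      ),
      class = "mir_lda"
    )
  } else if (identical(obj$family, "mir_svm")) {
    machines <- purrr::map(obj$machines, function(m) {
      m$w <- as.numeric(m$w)
      m$alpha <- as.numeric(m$alpha)
      m$sv_index <- as.integer(m$sv_index)
      m
    })
    structure(
      list(
        formulation = obj$formulation, cost = obj$cost, nu = obj$nu,
        labels = obj$labels, machines = machines,
        wavenumbers = obj$wavenumbers,
        center = obj$center, scale_sd = obj$scale_sd
      ),
      class = "mir_svm"
    )
  } else {
    rlang::abort("Unrecognized model JSON (no known 'family' field).")
  }
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  ph <- config$phantom
  obj <- list(
    phantom = list(
      grid = list(start_cm1 = ph$grid$start_cm1, end_cm1 = ph$grid$end_cm1,
                  step_cm1 = ph$grid$step_cm1),
      image_width_px = ph$image_width_px,
      image_height_px = ph$image_height_px,
      pixel_size_um = ph$pixel_size_um,
      patients_per_class = ph$patients_per_class,
      signatures = purrr::map(ph$signatures, function(s) {
        purrr::transpose(as.list(s$bands))
      }),
      patient_amplitude_sd = ph$patient_amplitude_sd,
      pixel_noise_sd = ph$pixel_noise_sd,
      baseline_order = ph$baseline_order,
      baseline_sd = ph$baseline_sd,
      atmospheric_level = ph$atmospheric_level,
      seed = ph$seed
    ),
    preprocess = list(n_factors = config$n_factors,
                      band = config$band,
                      atmospheric = config$atmospheric),
    models = list(names = config$models, cost = config$cost, nu = config$nu,
                  ridge_eps = config$ridge_eps),
    evaluate = list(cutoffs = config$cutoffs, vote_pool = config$vote_pool)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  ph <- obj$phantom %||% list()
  defaults <- phantom_config()
  grid <- if (is.null(ph$grid)) defaults$grid else {
    wn_grid(ph$grid$start_cm1, ph$grid$end_cm1, ph$grid$step_cm1)
  }
  signatures <- if (is.null(ph$signatures)) default_signatures() else {
    purrr::imap(ph$signatures, function(bands, subtype) {
      ir_signature(subtype, purrr::map_dfr(bands, tibble::as_tibble))
    })
  }
  pick <- function(x, d) if (is.null(x)) d else x
  phantom <- phantom_config(
    grid = grid,
    image_width_px = pick(ph$image_width_px, defaults$image_width_px),
    image_height_px = pick(ph$image_height_px, defaults$image_height_px),
    pixel_size_um = pick(ph$pixel_size_um, defaults$pixel_size_um),
    patients_per_class = pick(ph$patients_per_class, defaults$patients_per_class),
    signatures = signatures,
    patient_amplitude_sd = pick(ph$patient_amplitude_sd, defaults$patient_amplitude_sd),
    pixel_noise_sd = pick(ph$pixel_noise_sd, defaults$pixel_noise_sd),
    baseline_order = pick(ph$baseline_order, defaults$baseline_order),
    baseline_sd = pick(ph$baseline_sd, defaults$baseline_sd),
    atmospheric_level = pick(ph$atmospheric_level, defaults$atmospheric_level),
    seed = pick(ph$seed, defaults$seed)
  )
  pre <- obj$preprocess %||% list()
  mod <- obj$models %||% list()
  ev <- obj$evaluate %||% list()
  run_config(
    phantom = phantom,
    n_factors = pick(pre$n_factors, 20),
    band = unlist(pick(pre$band, c(1800, 648))),
    atmospheric = pick(pre$atmospheric, phantom$atmospheric_level > 0),
    models = unlist(pick(mod$names, model_names())),
    cost = pick(mod$cost, 1), nu = pick(mod$nu, 0.5),
    ridge_eps = pick(mod$ridge_eps, 1e-6),
    cutoffs = unlist(pick(ev$cutoffs, c(0.50, 0.60, 0.70, 0.80, 0.90, 0.95))),
    vote_pool = pick(ev$vote_pool, "test")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
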