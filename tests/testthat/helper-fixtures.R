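# Small fixture builders; all data is generated in code at test time.

tiny_phantom <- function(width = 6, height = 4, ppc = 2, seed = 1, ...) {
  phantom_config(
    image_width_px = width, image_height_px = height,
    patients_per_class = ppc, seed = seed, ...
  )
}

# Noise-free configuration: pixels are exact copies of the class signature.
noise_free_phantom <- function(width = 4, height = 3, ppc = 1, seed = 1) {
  tiny_phantom(width, height, ppc, seed,
               patient_amplitude_sd = 0, pixel_noise_sd = 0,
               baseline_sd = 0, atmospheric_level = 0)
}

# Wrap a plain matrix as a spectra table; labels must be subtype labels.
toy_table <- function(X, labels, role = "train", patient_id = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(p >= 2)
  grid <- wn_grid(1800, 1800 - 8 * (p - 1), 8)
  if (is.null(patient_id)) patient_id <- paste0("P", seq_len(nrow(X)))
  meta <- tibble::tibble(
    patient_id = patient_id,
    subtype = labels,
    row = 0L,
    col = seq_len(nrow(X)) - 1L,
    role = rep_len(role, nrow(X))
  )
  spectra_table(meta, X, grid)
}

# Random spectra table on an arbitrary fingerprint-style grid.
random_table <- function(n, p, seed = 1, labels = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  if (is.null(labels)) labels <- rep_len(subtype_levels(), n)
  toy_table(X, labels)
}

# Linearly separable 2-D three-class toy lifted into p >= 2 channels.
separable_3class <- function(per_class = 4, p = 2, seed = 1, spread = 0.3) {
  set.seed(seed)
  centers <- rbind(SQ = c(0, 4), LUAD = c(4, 0), SCLC = c(-4, -4))
  X <- do.call(rbind, lapply(rownames(centers), function(l) {
    sweep(matrix(rnorm(per_class * 2, 0, spread), per_class, 2), 2,
          centers[l, ], `+`)
  }))
  if (p > 2) X <- cbind(X, matrix(0, nrow(X), p - 2))
  list(X = X, y = rep(rownames(centers), each = per_class))
}
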