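#' Wavenumber grid
#'
#' The spectral axis shared by all spectra in a study: a descending,
#' evenly spaced sequence of wavenumbers (cm^-1) from `start_cm1` down to
#' `end_cm1` in steps of `step_cm1`. Channel `k` (1-based) holds
#' `start_cm1 - (k - 1) * step_cm1`.
#'
#' @param start_cm1 First (highest) wavenumber, cm^-1.
#' @param end_cm1 Last (lowest) wavenumber, cm^-1. Must be below `start_cm1`.
#' @param step_cm1 Data interval, cm^-1, positive; must divide
#'   `start_cm1 - end_cm1` exactly.
#'
#' @return An object of class `wn_grid` with fields `start_cm1`, `end_cm1`,
#'   `step_cm1` and `n_channels`.
#'
#' @examples
#' g <- wn_grid(4000, 648, 8)   # the acquisition grid: 420 channels
#' g$n_channels
#' head(wn_values(g))
#' @export
wn_grid <- function(start_cm1, end_cm1, step_cm1) {
  stopifnot(
    is.numeric(start_cm1), length(start_cm1) == 1L, is.finite(start_cm1),
    is.numeric(end_cm1), length(end_cm1) == 1L, is.finite(end_cm1),
    is.numeric(step_cm1), length(step_cm1) == 1L, is.finite(step_cm1)
  )
  if (start_cm1 <= end_cm1) {
    rlang::abort("`start_cm1` must be greater than `end_cm1` (descending axis).")
  }
  if (step_cm1 <= 0) {
    rlang::abort("`step_cm1` must be positive.")
  }
  span <- start_cm1 - end_cm1
  k <- span / step_cm1
  if (abs(k - round(k)) > 1e-9) {
    rem <- span - floor(k) * step_cm1
    rlang::abort(sprintf(
      "`step_cm1` (%g) does not divide the span %g - %g exactly (remainder %g).",
      step_cm1, start_cm1, end_cm1, rem
    ))
  }
  structure(
    list(
      start_cm1 = as.numeric(start_cm1),
      end_cm1 = as.numeric(end_cm1),
      step_cm1 = as.numeric(step_cm1),
      n_channels = as.integer(round(k) + 1)
    ),
    class = "wn_grid"
  )
}

#' Wavenumber values of a grid
#'
#' @param grid A [wn_grid()].
#' @return Numeric vector of length `n_channels`, descending.
#' @export
wn_values <- function(grid) {
  stopifnot(inherits(grid, "wn_grid"))
  grid$start_cm1 - (seq_len(grid$n_channels) - 1) * grid$step_cm1
}

#' @export
print.wn_grid <- function(x, ...) {
  cat(sprintf(
    "<wn_grid> %g -> %g cm^-1, step %g cm^-1 (%d channels)\n",
    x$start_cm1, x$end_cm1, x$step_cm1, x$n_channels
  ))
  invisible(x)
}

#' @export
format.wn_grid <- function(x, ...) {
  sprintf("%g:%g:%g", x$start_cm1, x$end_cm1, x$step_cm1)
}

# Reconstruct a wn_grid from a descending, evenly spaced wavenumber vector.
# Used when a grid travels as matrix-column names (see spectra tables).
grid_from_values <- function(wn) {
  wn <- as.numeric(wn)
  if (length(wn) < 2L) {
    rlang::abort("Need at least two wavenumbers to reconstruct a grid.")
  }
  steps <- -diff(wn)
  if (any(steps <= 0) || diff(range(steps)) > 1e-6) {
    rlang::abort("Wavenumbers are not descending and evenly spaced.")
  }
  wn_grid(wn[1], wn[length(wn)], mean(steps))
}

grids_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-9))
}
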