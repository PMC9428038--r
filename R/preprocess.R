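#' Atmospheric reference spectra
#'
#' Synthesizes the CO2 and H2O vapour reference spectra used both to
#' contaminate phantoms and as the basis for least-squares suppression.
#' Line lists are shipped as an editable YAML file (one band set per
#' species); the references themselves are synthetic, since no vendor
#' reference spectra are distributed with this package.
#'
#' @param grid A [wn_grid()] on which to evaluate the references.
#' @param path YAML line-list file; defaults to the shipped one.
#' @return Object of class `atm_refs`: `references` (species x channels
#'   matrix, row names = species), `species`, and the grid.
#' @export
atmospheric_references <- function(grid,
                                   path = system.file("extdata", "atmospheric_bands.yaml",
                                                      package = "mirlung")) {
  stopifnot(inherits(grid, "wn_grid"))
  spec <- yaml::read_yaml(path)
  wn <- wn_values(grid)
  refs <- t(vapply(spec, function(bands) {
    eval_bands(purrr::map_dfr(bands, tibble::as_tibble), wn)
  }, numeric(length(wn))))
  dead <- rowSums(abs(refs)) == 0
  if (any(dead)) {
    rlang::abort(paste0("Reference species evaluate to zero on this grid: ",
                        paste(names(spec)[dead], collapse = ", ")))
  }
  structure(
    list(references = refs, species = names(spec), grid = grid),
    class = "atm_refs"
  )
}

#' @export
print.atm_refs <- function(x, ...) {
  cat(sprintf("<atm_refs> %s on %s (%d channels)\n",
              paste(x$species, collapse = ", "), format(x$grid),
              x$grid$n_channels))
  invisible(x)
}

#' Least-squares atmospheric suppression
#'
#' For each spectrum `s`, fits `s ~ offset + sum_j beta_j * reference_j` by
#' ordinary least squares and subtracts the fitted reference contribution
#' (the offset is retained, so baseline level is untouched). Any spectrum
#' lying in the span of the references (plus a constant) is annihilated up
#' to that constant.
#'
#' @param table A spectra table (see [spectra_table()]).
#' @param references An [atmospheric_references()] object on the same grid.
#' @return The corrected table, with an additional matrix column
#'   `atmospheric_coef` holding the fitted per-spectrum coefficients
#'   (one column per species).
#' @export
atmospheric_correct <- function(table, references) {
  stopifnot(inherits(references, "atm_refs"))
  if (!grids_equal(spc_grid(table), references$grid)) {
    rlang::abort("References are not on the table's wavenumber grid.")
  }
  R <- references$references                      # m x n
  X <- cbind(offset = 1, t(R))                    # n x (m+1)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])
    bad <- colnames(X)[drop]
    rlang::abort(paste0("Reference set is rank-deficient; collinear column(s): ",
                        paste(bad, collapse = ", ")))
  }
  S <- spc_matrix(table)                          # N x n
  beta <- qr.coef(qx, t(S))                       # (m+1) x N
  contrib <- t(beta[-1, , drop = FALSE]) %*% R    # N x n
  out <- set_spc_matrix(table, S - contrib)
  coefs <- t(beta[-1, , drop = FALSE])
  colnames(coefs) <- references$species
  out$atmospheric_coef <- coefs
  out
}

#' PCA noise reduction by truncated reconstruction
#'
#' Mean-centers the spectra over rows (subtracting the grand mean spectrum),
#' reconstructs each spectrum from the top `n_factors` principal components,
#' and adds the mean back. Because noise loads on low-variance components,
#' the 20-factor reconstruction is noise-reduced while — unlike smoothing —
#' leaving peak widths intact. If `n_factors` reaches the rank of the
#' centered matrix the operation is the identity.
#'
#' @param table A spectra table with at least 2 rows.
#' @param n_factors Number of principal components retained (default 20).
#' @param by_patient If `TRUE`, fit and reconstruct each patient's spectra
#'   separately; the default (`FALSE`) treats the whole table jointly.
#' @return The denoised table. The fitted summary is attached as attribute
#'   `"denoise_report"` (see [denoise_report()]): number of factors used,
#'   the fraction of variance captured per retained factor (descending),
#'   the grand mean spectrum, and sign-fixed loadings.
#' @export
pca_denoise <- function(table, n_factors = 20, by_patient = FALSE) {
  if (n_factors < 1) rlang::abort("`n_factors` must be >= 1.")
  if (nrow(table) < 2) rlang::abort("Need at least 2 spectra to denoise.")
  if (by_patient) {
    ids <- unique(table$patient_id)
    reports <- list()
    out <- table
    for (id in ids) {
      idx <- which(table$patient_id == id)
      sub <- pca_denoise_matrix(spc_matrix(table)[idx, , drop = FALSE], n_factors)
      out$absorbance[idx, ] <- sub$m
      reports[[id]] <- sub$report
    }
    attr(out, "denoise_report") <- reports
    return(out)
  }
  res <- pca_denoise_matrix(spc_matrix(table), n_factors)
  out <- set_spc_matrix(table, res$m)
  attr(out, "denoise_report") <- res$report
  out
}

pca_denoise_matrix <- function(X, n_factors) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- svd(Xc)
  tol <- max(dim(Xc)) * max(s$d) * .Machine$double.eps
  rank <- sum(s$d > tol)
  k <- min(n_factors, rank)
  if (k == 0) {
    # centered matrix is zero: reconstruction is just the mean
    m <- sweep(0 * X, 2, mu, `+`)
    report <- new_denoise_report(0L, numeric(0), mu, matrix(0, ncol(X), 0))
    return(list(m = m, report = report))
  }
  U <- s$u[, seq_len(k), drop = FALSE]
  V <- s$v[, seq_len(k), drop = FALSE]
  d <- s$d[seq_len(k)]
  m <- sweep(U %*% (d * t(V)), 2, mu, `+`)
  # deterministic component signs: largest-magnitude loading positive
  flip <- vapply(seq_len(k), function(j) {
    v <- V[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  V <- sweep(V, 2, flip, `*`)
  report <- new_denoise_report(
    as.integer(k),
    (d^2 / sum(s$d^2)),
    mu,
    V
  )
  list(m = m, report = report)
}

new_denoise_report <- function(n_factors, variance_captured, grand_mean, loadings) {
  structure(
    list(
      n_factors = n_factors,
      variance_captured = variance_captured,
      grand_mean = grand_mean,
      loadings = loadings
    ),
    class = "denoise_report"
  )
}

#' @export
print.denoise_report <- function(x, ...) {
  cat(sprintf("<denoise_report> %d factors, %.2f%% variance captured\n",
              x$n_factors, 100 * sum(x$variance_captured)))
  invisible(x)
}

#' Retrieve the denoise report attached by [pca_denoise()]
#' @param table A table returned by [pca_denoise()].
#' @return A `denoise_report` (or a per-patient list of them).
#' @export
denoise_report <- function(table) {
  rep <- attr(table, "denoise_report")
  if (is.null(rep)) rlang::abort("No denoise report attached to this table.")
  rep
}

#' Restrict a table to the fingerprint region
#'
#' Keeps the channels with `low_cm1 <= wavenumber <= high_cm1` (both bounds
#' inclusive; on the 4000–648 cm^-1 step-8 grid the default 1800–648 window
#' retains exactly 145 wavenumbers). Channel order (descending) and row
#' metadata are untouched.
#'
#' @param table A spectra table.
#' @param high_cm1,low_cm1 Inclusive bounds, cm^-1 (defaults 1800 and 648).
#' @return The restricted table.
#' @export
slice_fingerprint <- function(table, high_cm1 = 1800, low_cm1 = 648) {
  if (high_cm1 < low_cm1) {
    rlang::abort("`high_cm1` must be >= `low_cm1`.")
  }
  wn <- spc_wavenumbers(table)
  keep <- wn >= low_cm1 & wn <= high_cm1
  if (!any(keep)) {
    rlang::abort(sprintf(
      "No channel falls inside [%g, %g] cm^-1 on this grid.", low_cm1, high_cm1
    ))
  }
  table$absorbance <- table$absorbance[, keep, drop = FALSE]
  table
}
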