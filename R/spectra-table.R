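#' Spectra tables
#'
#' The flattened, analysis-ready form of a cohort: a tibble with one row per
#' pixel spectrum and columns
#' `patient_id`, `subtype` (factor with levels SQ, LUAD, SCLC),
#' `row`, `col` (0-based pixel coordinates), `role`
#' (`"train"`, `"test"` or `"unassigned"`), and `absorbance` — a matrix
#' column whose column names are the grid wavenumbers (descending). Keeping
#' the spectral axis in the matrix column's names lets ordinary dplyr verbs
#' (filter, arrange, mutate) operate on the table without losing the grid.
#'
#' @param meta A data frame with columns patient_id, subtype, row, col and
#'   optionally role.
#' @param absorbance Numeric matrix, `nrow(meta)` x n_channels.
#' @param grid The [wn_grid()] of the channels.
#' @return A tibble as described above.
#' @export
spectra_table <- function(meta, absorbance, grid) {
  stopifnot(inherits(grid, "wn_grid"))
  absorbance <- as.matrix(absorbance)
  if (nrow(meta) != nrow(absorbance)) {
    rlang::abort("Metadata and spectra row counts differ.")
  }
  if (ncol(absorbance) != grid$n_channels) {
    rlang::abort("Spectra column count does not match the grid.")
  }
  if (!all(is.finite(absorbance))) {
    rlang::abort("Absorbance values must all be finite.")
  }
  colnames(absorbance) <- format_wn(wn_values(grid))
  meta <- tibble::as_tibble(meta)
  if (!"role" %in% names(meta)) meta$role <- "unassigned"
  keys <- paste(meta$patient_id, meta$row, meta$col)
  if (anyDuplicated(keys)) {
    rlang::abort("(patient_id, row, col) must be unique across rows.")
  }
  out <- meta[, c("patient_id", "subtype", "row", "col", "role")]
  out$subtype <- as_subtype(out$subtype)
  out$absorbance <- absorbance
  out
}

format_wn <- function(wn) sprintf("%.10g", wn)

as_subtype <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  bad <- setdiff(unique(x), subtype_levels())
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown subtype label(s): ", paste(bad, collapse = ", ")))
  }
  factor(x, levels = subtype_levels())
}

#' Wavenumbers of a spectra table
#' @param table A spectra table (see [spectra_table()]).
#' @return Numeric descending wavenumber vector.
#' @export
spc_wavenumbers <- function(table) {
  as.numeric(colnames(spc_matrix(table)))
}

#' Absorbance matrix of a spectra table
#' @param table A spectra table.
#' @return Numeric matrix, rows = spectra, columns = channels (descending
#'   wavenumber; column names carry the wavenumbers).
#' @export
spc_matrix <- function(table) {
  if (!"absorbance" %in% names(table) || !is.matrix(table$absorbance)) {
    rlang::abort("Not a spectra table: no `absorbance` matrix column.")
  }
  table$absorbance
}

#' Grid of a spectra table
#' @param table A spectra table.
#' @return The [wn_grid()] reconstructed from the matrix column.
#' @export
spc_grid <- function(table) {
  grid_from_values(spc_wavenumbers(table))
}

# Replace the absorbance matrix, keeping wavenumber names.
set_spc_matrix <- function(table, m) {
  colnames(m) <- colnames(table$absorbance)
  table$absorbance <- m
  table
}

#' Flatten a cohort into a spectra table
#'
#' Emits every pixel spectrum of every cube as one row: pixels in row-major
#' order within a patient ((0,0), (0,1), ..., left-to-right then
#' top-to-bottom), patients in cohort order. All cubes must share one grid.
#' The `role` column is `"unassigned"`; see [split_alternating()].
#'
#' @param cohort A [generate_cohort()] result, or any list of
#'   `spectral_cube`s in a `$cubes` field.
#' @return A spectra table with `n_cubes * width * height` rows.
#' @export
flatten_cohort <- function(cohort) {
  cubes <- if (inherits(cohort, "patient_cohort")) cohort$cubes else cohort
  if (length(cubes) == 0) rlang::abort("Cohort is empty.")
  g0 <- cubes[[1]]$grid
  same <- purrr::map_lgl(cubes, ~ grids_equal(.x$grid, g0))
  if (!all(same)) {
    rlang::abort("Cubes are on different wavenumber grids; cannot flatten.")
  }
  pieces <- purrr::map(cubes, function(cube) {
    d <- dim(cube$absorbance)
    m <- matrix(aperm(cube$absorbance, c(2, 1, 3)), nrow = d[1] * d[2])
    meta <- tibble::tibble(
      patient_id = cube$patient_id,
      subtype = cube$subtype,
      row = rep(0:(d[1] - 1), each = d[2]),
      col = rep(0:(d[2] - 1), times = d[1])
    )
    list(meta = meta, m = m)
  })
  spectra_table(
    dplyr::bind_rows(purrr::map(pieces, "meta")),
    do.call(rbind, purrr::map(pieces, "m")),
    g0
  )
}

#' Plot mean spectra by subtype
#'
#' @param object A spectra table.
#' @param ... Unused.
#' @return A ggplot: mean absorbance per subtype over wavenumber, axis
#'   reversed as is conventional for IR spectra.
#' @export
plot_mean_spectra <- function(object, ...) {
  wn <- spc_wavenumbers(object)
  m <- spc_matrix(object)
  df <- dplyr::group_by(
    tibble::tibble(subtype = object$subtype, i = seq_len(nrow(object))),
    .data$subtype
  )
  means <- dplyr::group_map(df, function(d, key) {
    tibble::tibble(
      subtype = key$subtype[[1]],
      wavenumber_cm1 = wn,
      absorbance = colMeans(m[d$i, , drop = FALSE])
    )
  })
  means <- dplyr::bind_rows(means)
  ggplot2::ggplot(means, ggplot2::aes(.data$wavenumber_cm1, .data$absorbance,
                                      colour = .data$subtype)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)),
                  y = "Mean absorbance (a.u.)", colour = "Subtype") +
    ggplot2::theme_minimal()
}
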