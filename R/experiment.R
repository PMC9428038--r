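#' Canonical model identifiers
#'
#' @return The five model names understood by [run_full_experiment()]:
#'   `lda_linear`, `lda_quadratic`, `lda_mahalanobis`, `svm_c`, `svm_nu`.
#' @export
model_names <- function() {
  c("lda_linear", "lda_quadratic", "lda_mahalanobis", "svm_c", "svm_nu")
}

fit_model <- function(name, table, cost = 1, nu = 0.5, ridge_eps = 1e-6) {
  switch(name,
    lda_linear = fit_discriminant(table, "linear", ridge_eps),
    lda_quadratic = fit_discriminant(table, "quadratic", ridge_eps),
    lda_mahalanobis = fit_discriminant(table, "mahalanobis", ridge_eps),
    svm_c = fit_margin(table, "c_svc", cost = cost),
    svm_nu = fit_margin(table, "nu_svc", nu = nu),
    rlang::abort(sprintf("Unknown model '%s'; choose among %s.", name,
                         paste(model_names(), collapse = ", ")))
  )
}

#' Run configuration for the full pipeline
#'
#' Bundles the phantom settings with the preprocessing, model and
#' evaluation choices of one experiment.
#'
#' @param phantom A [phantom_config()].
#' @param n_factors PCA denoising factors (default 20).
#' @param band Fingerprint window, `c(high, low)` in cm^-1
#'   (default `c(1800, 648)`).
#' @param atmospheric Apply least-squares CO2/H2O suppression? Default:
#'   on exactly when the phantom adds contamination.
#' @param models Model identifiers (see [model_names()]).
#' @param cost,nu,ridge_eps Hyperparameters forwarded to the classifiers.
#' @param cutoffs Patient-vote cut-offs, fractions in (0, 1].
#' @param vote_pool `"test"` (default) computes patient fractions over held
#'   out spectra only; `"all"` uses every spectrum, training included
#'   (optimistic: training fit leaks into the patient vote).
#' @return An object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_config(),
                       n_factors = 20,
                       band = c(1800, 648),
                       atmospheric = phantom$atmospheric_level > 0,
                       models = model_names(),
                       cost = 1, nu = 0.5, ridge_eps = 1e-6,
                       cutoffs = c(0.50, 0.60, 0.70, 0.80, 0.90, 0.95),
                       vote_pool = c("test", "all")) {
  vote_pool <- rlang::arg_match(vote_pool)
  stopifnot(inherits(phantom, "phantom_config"), length(band) == 2)
  bad <- setdiff(models, model_names())
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown model(s): ", paste(bad, collapse = ", ")))
  }
  if (length(models) == 0) rlang::abort("`models` must not be empty.")
  structure(
    list(
      phantom = phantom, n_factors = n_factors, band = as.numeric(band),
      atmospheric = isTRUE(atmospheric), models = models,
      cost = cost, nu = nu, ridge_eps = ridge_eps,
      cutoffs = cutoffs, vote_pool = vote_pool
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> %d models [%s], %d-factor denoise, band %g-%g, atmospheric %s, vote over %s spectra, seed %d\n",
    length(x$models), paste(x$models, collapse = ", "), x$n_factors,
    x$band[1], x$band[2], ifelse(x$atmospheric, "on", "off"), x$vote_pool,
    x$phantom$seed
  ))
  invisible(x)
}

#' Run the full phantom-to-evaluation experiment
#'
#' Executes the whole pipeline: generate the phantom cohort, flatten,
#' optionally suppress atmospheric CO2/H2O, denoise by truncated PCA
#' reconstruction, slice the fingerprint window, assign the alternating
#' train/test split, then fit and apply every requested model and evaluate
#' both regimes — pixel-based confusion-matrix metrics and the
#' patient-based cut-off vote.
#'
#' @param config A [run_config()].
#' @return Object of class `mir_experiment`: `config`, `predictions`
#'   (metadata + `.pred` per model, vote-pool rows), `confusions` (list per
#'   model over test rows), `metrics` (per model x class tibble),
#'   `fractions` (per model x patient), `sweep` (per model x cut-off x
#'   subtype), `denoise` report, and the seed.
#' @examples
#' \donttest{
#' cfg <- run_config(
#'   phantom = phantom_config(image_width_px = 8, image_height_px = 4,
#'                            patients_per_class = 2, seed = 42),
#'   models = "svm_c"
#' )
#' ex <- run_full_experiment(cfg)
#' ex$sweep
#' }
#' @export
run_full_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(config$phantom)
  tbl <- flatten_cohort(cohort)
  if (config$atmospheric) {
    refs <- atmospheric_references(spc_grid(tbl))
    tbl <- atmospheric_correct(tbl, refs)
  }
  tbl <- pca_denoise(tbl, n_factors = config$n_factors)
  report <- denoise_report(tbl)
  tbl <- slice_fingerprint(tbl, config$band[1], config$band[2])
  tbl <- split_alternating(tbl)

  meta_cols <- c("patient_id", "subtype", "row", "col", "role")
  test_tbl <- dplyr::filter(tbl, .data$role == "test")
  pool_tbl <- if (config$vote_pool == "all") tbl else test_tbl

  per_model <- purrr::map(config$models, function(name) {
    model <- fit_model(name, tbl, cost = config$cost, nu = config$nu,
                       ridge_eps = config$ridge_eps)
    pool_pred <- augment(model, pool_tbl)[c(meta_cols, ".pred", "model")]
    test_pred <- if (config$vote_pool == "all") {
      dplyr::filter(pool_pred, .data$role == "test")
    } else {
      pool_pred
    }
    list(
      name = name,
      predictions = pool_pred,
      confusion = confusion(test_pred),
      metrics = dplyr::mutate(class_metrics(confusion(test_pred)),
                              model = name, .before = 1),
      fractions = dplyr::mutate(patient_fractions(pool_pred),
                                model = name, .before = 1)
    )
  })

  fractions <- dplyr::bind_rows(purrr::map(per_model, "fractions"))
  structure(
    list(
      config = config,
      predictions = dplyr::bind_rows(purrr::map(per_model, "predictions")),
      confusions = stats::setNames(purrr::map(per_model, "confusion"),
                                   config$models),
      metrics = dplyr::bind_rows(purrr::map(per_model, "metrics")),
      fractions = fractions,
      sweep = cutoff_sweep(fractions, config$cutoffs),
      denoise = report,
      seed = config$phantom$seed
    ),
    class = "mir_experiment"
  )
}

#' @export
print.mir_experiment <- function(x, ...) {
  cat(sprintf("<mir_experiment> %d models, %d spectra predicted, seed %d\n",
              length(x$confusions), nrow(x$predictions), x$seed))
  print(glance(x))
  invisible(x)
}

#' One-row-per-model experiment summary
#'
#' @param x A `mir_experiment`.
#' @param ... Unused.
#' @return Tibble: model, pixel accuracy over test spectra, and mean
#'   patient-based accuracy at the 50% cut-off.
#' @export
glance.mir_experiment <- function(x, ...) {
  pixel <- purrr::imap_dfr(x$confusions, function(cm, name) {
    tibble::tibble(model = name,
                   pixel_accuracy = sum(diag(cm)) / sum(cm))
  })
  at50 <- x$sweep |>
    dplyr::filter(abs(.data$cutoff - 0.5) < 1e-9) |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(patient_accuracy_50 = mean(.data$accuracy))
  dplyr::left_join(pixel, at50, by = "model")
}

#' Plot an experiment's cut-off sweep
#'
#' @param object A `mir_experiment`.
#' @param ... Unused.
#' @return ggplot; see [plot_cutoff_sweep()].
#' @export
autoplot.mir_experiment <- function(object, ...) {
  plot_cutoff_sweep(object$sweep)
}
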