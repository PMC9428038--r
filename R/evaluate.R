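#' Confusion matrix of a prediction table
#'
#' Tallies true versus predicted subtype over the rows of a prediction
#' table (a spectra table augmented with a `.pred` column). Label order is
#' fixed to (SQ, LUAD, SCLC); rows are the true label, columns the
#' prediction.
#'
#' @param predictions A tibble with `subtype` (truth) and `.pred` columns.
#' @return A K x K integer matrix of class `mir_confusion`.
#' @export
confusion <- function(predictions) {
  if (nrow(predictions) == 0) rlang::abort("Prediction table is empty.")
  truth <- as_subtype(predictions$subtype)
  pred <- as_subtype(predictions$.pred)
  cm <- base::table(truth = truth, predicted = pred)
  cm <- unclass(cm)[subtype_levels(), subtype_levels()]
  structure(cm, class = c("mir_confusion", class(cm)))
}

#' @export
print.mir_confusion <- function(x, ...) {
  cat("<mir_confusion> rows = truth, columns = predicted\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class one-vs-rest metrics from a confusion matrix
#'
#' For each class k: TP = cm[k,k]; FN = rest of row k; FP = rest of column
#' k; TN = everything else. Sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' positive predictive value TP/(TP+FP), negative predictive value
#' TN/(TN+FN). Undefined ratios (0/0) are reported as `NA`, never as 0.
#'
#' @param cm A [confusion()] matrix (or any K x K count matrix with
#'   dimnames, K >= 2).
#' @return Tibble with columns class, sensitivity, specificity, ppv, npv.
#' @export
class_metrics <- function(cm) {
  cm <- unclass(cm)
  if (nrow(cm) < 2 || nrow(cm) != ncol(cm)) {
    rlang::abort("Need a square confusion matrix with K >= 2.")
  }
  total <- sum(cm)
  safe_div <- function(a, b) ifelse(b == 0, NA_real_, a / b)
  purrr::map_dfr(seq_len(nrow(cm)), function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    tibble::tibble(
      class = rownames(cm)[k],
      sensitivity = safe_div(tp, tp + fn),
      specificity = safe_div(tn, tn + fp),
      ppv = safe_div(tp, tp + fp),
      npv = safe_div(tn, tn + fn)
    )
  })
}

#' Per-patient correct-classification fractions
#'
#' For each patient, the fraction of their spectra predicted as the
#' patient's true subtype — the quantity thresholded by the cut-off vote.
#'
#' @param predictions A prediction tibble (`patient_id`, `subtype`, `.pred`).
#' @return Tibble: patient_id, subtype, n_spectra, fraction.
#' @export
patient_fractions <- function(predictions) {
  if (nrow(predictions) == 0) rlang::abort("Prediction table is empty.")
  bad <- predictions |>
    dplyr::distinct(.data$patient_id, .data$subtype) |>
    dplyr::count(.data$patient_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(bad) > 0) {
    rlang::abort(paste0("Patient(s) with inconsistent true labels: ",
                        paste(bad$patient_id, collapse = ", ")))
  }
  predictions |>
    dplyr::group_by(.data$patient_id, .data$subtype) |>
    dplyr::summarise(
      n_spectra = dplyr::n(),
      fraction = mean(.data$.pred == .data$subtype),
      .groups = "drop"
    )
}

#' Patient-level accuracy across classification cut-offs
#'
#' A patient counts as correctly classified at cut-off `c` when their
#' correct-spectrum fraction is at least `c` (a patient exactly at the
#' cut-off passes). Tallies are reported per subtype as numerator and
#' denominator, the form in which patient-based accuracy is conventionally
#' printed (k/10).
#'
#' @param fractions A [patient_fractions()] tibble (a `model` column, if
#'   present, is carried through and swept separately).
#' @param cutoffs Fractions in (0, 1]; default
#'   `c(0.50, 0.60, 0.70, 0.80, 0.90, 0.95)`.
#' @return Tibble: (model,) cutoff, subtype, n_correct, n_total, accuracy.
#'   For fixed model and subtype `n_correct` is non-increasing in the
#'   cut-off.
#' @export
cutoff_sweep <- function(fractions, cutoffs = c(0.50, 0.60, 0.70, 0.80, 0.90, 0.95)) {
  if (nrow(fractions) == 0) rlang::abort("No patient vote results.")
  if (any(cutoffs <= 0 | cutoffs > 1)) {
    rlang::abort("Cut-offs must lie in (0, 1].")
  }
  groups <- intersect(c("model", "subtype"), names(fractions))
  purrr::map_dfr(sort(cutoffs), function(co) {
    fractions |>
      dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
      dplyr::summarise(
        cutoff = co,
        n_correct = sum(.data$fraction >= co),
        n_total = dplyr::n(),
        .groups = "drop"
      )
  }) |>
    dplyr::mutate(accuracy = .data$n_correct / .data$n_total) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(
      intersect("model", groups), "cutoff"
    ))))
}

#' Plot a cut-off sweep
#'
#' @param object A [cutoff_sweep()] tibble.
#' @param ... Unused.
#' @return ggplot of patient-level accuracy against cut-off, one line per
#'   subtype, faceted by model when present.
#' @export
plot_cutoff_sweep <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$cutoff, .data$accuracy,
                                            colour = .data$subtype)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "Cut-off", y = "Patient-based accuracy",
                  colour = "Subtype") +
    ggplot2::theme_minimal()
  if ("model" %in% names(object)) p <- p + ggplot2::facet_wrap(~model)
  p
}
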