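#' Alternating train/test split
#'
#' Assigns every second spectrum to the training set: within each patient,
#' in the table's (flatten) row order, spectra at even 0-based positions
#' become `"train"` and odd positions `"test"`. Splitting per patient keeps
#' both halves balanced within every patient, which the patient-level vote
#' relies on; per patient the two halves differ in size by at most one row.
#'
#' @param table A spectra table (see [flatten_cohort()]).
#' @return The table with `role` filled in.
#' @export
split_alternating <- function(table) {
  if (nrow(table) == 0) return(table)
  table |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(role = ifelse((dplyr::row_number() - 1) %% 2 == 0,
                                "train", "test")) |>
    dplyr::ungroup()
}
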