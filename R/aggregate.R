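#' Aggregate one patient's chest-position labels to a patient label
#'
#' A patient is abnormal if one or more interpretable positions are abnormal,
#' uninterpretable if no position is interpretable, and normal otherwise
#' (including the mixed case of interpretable-normal plus uninterpretable
#' positions).
#'
#' @param labels A data frame with columns `interpretable`, `status` — one
#'   row per rated position for one patient (1 to 6 rows; missing recordings
#'   are simply absent).
#' @return A one-row tibble: `status`, `n_positions_total`, `n_interpretable`,
#'   `n_abnormal`.
#' @export
aggregate_patient <- function(labels) {
  n <- nrow(labels)
  if (is.null(n) || n < 1L) stop("no position labels supplied", call. = FALSE)
  if (n > 6L) stop("more than 6 positions for one patient", call. = FALSE)
  n_interp <- sum(labels$interpretable)
  n_abn <- sum(labels$interpretable & labels$status == "abnormal", na.rm = TRUE)
  status <- if (n_interp == 0L) "uninterpretable"
            else if (n_abn >= 1L) "abnormal" else "normal"
  tibble::tibble(status = status, n_positions_total = n,
                 n_interpretable = n_interp, n_abnormal = n_abn)
}

#' Aggregate every patient in a stream of final labels
#'
#' @param final_labels A tibble with `patient_id`, `interpretable`, `status`
#'   (e.g. the output of [adjudicate_study()]).
#' @return A tibble with one row per patient: `patient_id`, `status`,
#'   `n_positions_total`, `n_interpretable`, `n_abnormal`.
#' @export
aggregate_patients <- function(final_labels) {
  out <- dplyr::group_modify(
    dplyr::group_by(tibble::as_tibble(final_labels), .data$patient_id),
    function(df, key) aggregate_patient(df))
  dplyr::ungroup(out)
}

#' Majority vote over classifier iterations
#'
#' Combines k binary normal/abnormal labels into the status held by more
#' than half of them. An exact tie (possible only for even k) is an error by
#' default; a tie-break status can be configured explicitly for sensitivity
#' analyses, and is never applied silently.
#'
#' @param labels Character vector of `"normal"`/`"abnormal"` from k
#'   iterations, k >= 1.
#' @param tie `"error"` (default), `"abnormal"`, or `"normal"`.
#' @return `"normal"` or `"abnormal"`.
#' @export
majority_vote <- function(labels, tie = c("error", "abnormal", "normal")) {
  tie <- match.arg(tie)
  labels <- tolower(as.character(labels))
  if (length(labels) < 1L) stop("need at least one label", call. = FALSE)
  if (!all(labels %in% c("normal", "abnormal"))) {
    stop("labels must be binary normal/abnormal", call. = FALSE)
  }
  n_abn <- sum(labels == "abnormal")
  k <- length(labels)
  if (n_abn * 2L == k) {
    if (tie == "error") {
      stop("exact tie among ", k, " iterations and no tie-break configured",
           call. = FALSE)
    }
    return(tie)
  }
  if (n_abn * 2L > k) "abnormal" else "normal"
}

#' Ensemble a stream of per-iteration ratings by majority vote
#'
#' @param dataset A `study_ratings` tibble; only `ai_iteration` rows are used.
#' @param tie Tie policy passed to [majority_vote()].
#' @return A `final_labels` tibble with provenance `"single_source"`.
#' @export
ensemble_iterations <- function(dataset, tie = c("error", "abnormal", "normal")) {
  tie <- match.arg(tie)
  dataset <- validate_ratings(dataset)
  ai <- dataset[dataset$role == "ai_iteration", ]
  if (nrow(ai) == 0L) stop("no ai_iteration ratings present", call. = FALSE)
  out <- dplyr::reframe(
    dplyr::group_by(ai, .data$patient_id, .data$position),
    interpretable = TRUE,
    status = majority_vote(.data$status, tie = tie),
    subtype = NA_character_,
    provenance = "single_source")
  class(out) <- c("final_labels", class(out))
  out
}

#' Pair two label streams for agreement analysis
#'
#' Restricts comparisons to recordings the reference panel deemed
#' interpretable. At position level, pairs are formed per chest position
#' over the interpretable positions present in both streams. At patient
#' level, both streams are aggregated with [aggregate_patients()] — the
#' index stream gated to panel-interpretable positions first — and patients
#' whose panel status is uninterpretable are dropped.
#'
#' @param final_panel Panel `final_labels` (carries interpretability; the
#'   reference).
#' @param other_stream `final_labels` for the index stream (AI ensemble or
#'   clinician); its `status` is used, its interpretability is not.
#' @param level `"position"` or `"patient"`.
#' @return A tibble of paired binary labels: key columns plus
#'   `reference_status`, `index_status`.
#' @export
build_comparison <- function(final_panel, other_stream,
                             level = c("position", "patient")) {
  level <- match.arg(level)
  panel <- tibble::as_tibble(final_panel)
  other <- tibble::as_tibble(other_stream)

  joined <- dplyr::inner_join(
    panel[, c("patient_id", "position", "interpretable", "status")],
    other[, c("patient_id", "position", "status")],
    by = c("patient_id", "position"), suffix = c("_ref", "_idx"))
  if (nrow(joined) == 0L) {
    stop("streams share no (patient, position) keys", call. = FALSE)
  }

  if (level == "position") {
    pairs <- joined[joined$interpretable, ]
    return(tibble::tibble(patient_id = pairs$patient_id,
                          position = pairs$position,
                          reference_status = pairs$status_ref,
                          index_status = pairs$status_idx))
  }

  pat_ref <- aggregate_patients(panel)
  idx_gated <- joined[joined$interpretable,
                      c("patient_id", "position", "status_idx")]
  names(idx_gated)[3] <- "status"
  idx_gated$interpretable <- TRUE
  pat_idx <- aggregate_patients(idx_gated)

  pairs <- dplyr::inner_join(pat_ref[, c("patient_id", "status")],
                             pat_idx[, c("patient_id", "status")],
                             by = "patient_id", suffix = c("_ref", "_idx"))
  pairs <- pairs[pairs$status_ref != "uninterpretable", ]
  tibble::tibble(patient_id = pairs$patient_id,
                 reference_status = pairs$status_ref,
                 index_status = pairs$status_idx)
}
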