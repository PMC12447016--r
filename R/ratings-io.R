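#' Assemble and validate a study ratings table
#'
#' A study dataset is a long-format table with one row per rater label on a
#' chest-position recording. Columns: `patient_id`, `position` (integer 1-6),
#' `rater_id`, `role` (primary / arbitrator1 / arbitrator2 / ai_iteration /
#' clinician), `interpretable`, `status`, `subtype`. Missing recordings are
#' represented by absence of rows, never by a sentinel label.
#'
#' @param ratings A data frame with the columns above.
#' @return A validated tibble of class `study_ratings`.
#' @seealso [read_ratings()], [write_ratings()]
#' @export
study_ratings <- function(ratings) {
  validate_ratings(tibble::as_tibble(ratings))
}

required_columns <- c("patient_id", "position", "rater_id", "role",
                      "interpretable", "status", "subtype")

#' Validate a ratings table against the label invariants
#'
#' Checks column presence, position range, role vocabulary, duplicate
#' (patient, position, rater) keys, and the per-row label invariants
#' (status absent iff uninterpretable; subtype only for abnormal).
#' Violations are reported with their row numbers.
#'
#' @param ratings A data frame of ratings.
#' @return The validated tibble, classed `study_ratings`, with canonical
#'   lower-case label columns and integer positions.
#' @export
validate_ratings <- function(ratings) {
  missing_cols <- setdiff(required_columns, names(ratings))
  if (length(missing_cols) > 0L) {
    stop("ratings table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(ratings)
  out$patient_id <- as.character(out$patient_id)
  out$rater_id <- as.character(out$rater_id)
  out$position <- as.integer(out$position)
  out$role <- tolower(as.character(out$role))
  out$status <- canon_label(out$status)
  out$subtype <- canon_label(out$subtype)
  out$interpretable <- canon_logical(out$interpretable)

  bad_pos <- which(is.na(out$position) | out$position < 1L | out$position > 6L)
  if (length(bad_pos) > 0L) {
    stop("position outside 1-6 at row(s): ", row_list(bad_pos), call. = FALSE)
  }
  bad_role <- which(!out$role %in% roles)
  if (length(bad_role) > 0L) {
    stop("unknown role at row(s): ", row_list(bad_role), call. = FALSE)
  }
  bad_interp <- which(is.na(out$interpretable))
  if (length(bad_interp) > 0L) {
    stop("interpretable must be true/false at row(s): ", row_list(bad_interp),
         call. = FALSE)
  }

  # vectorised label invariants (same rules as label_violation())
  bad <- which(
    (!out$interpretable & !is.na(out$status)) |
    (out$interpretable &
       (is.na(out$status) | !out$status %in% c("normal", "abnormal"))) |
    (!is.na(out$subtype) &
       (is.na(out$status) | out$status != "abnormal" |
        !out$subtype %in% c("wheeze", "crackle", "both"))))
  if (length(bad) > 0L) {
    i <- bad[1]
    stop("invalid label at row(s) ", row_list(bad), ": ",
         label_violation(out$interpretable[i], out$status[i], out$subtype[i]),
         call. = FALSE)
  }

  key <- paste(out$patient_id, out$position, out$rater_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop("duplicate (patient, position, rater) at row(s): ", row_list(dup),
         call. = FALSE)
  }
  class(out) <- c("study_ratings", class(out))
  out
}

canon_label <- function(x) {
  x <- tolower(as.character(x))
  x[x %in% c("na", "")] <- NA_character_
  x
}

canon_logical <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1")] <- TRUE
  out[x %in% c("false", "f", "0")] <- FALSE
  out
}

row_list <- function(idx, max_show = 10L) {
  shown <- utils::head(idx, max_show)
  txt <- paste(shown, collapse = ", ")
  if (length(idx) > max_show) txt <- paste0(txt, ", ...")
  txt
}

#' Read a long-format ratings CSV
#'
#' @param path Path to a CSV with header. Column values are matched
#'   case-insensitively and canonicalised to lower case.
#' @param schema Optional named character vector mapping the canonical column
#'   names (`patient_id`, `position`, ...) to the names used in the file,
#'   e.g. `c(patient_id = "pid")`.
#' @return A validated `study_ratings` tibble.
#' @export
read_ratings <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      file_col <- schema[[canonical]]
      if (!file_col %in% names(raw)) {
        stop("schema column '", file_col, "' not present in file",
             call. = FALSE)
      }
      names(raw)[names(raw) == file_col] <- canonical
    }
  }
  validate_ratings(raw)
}

#' Write a ratings table to CSV
#'
#' Writes the long format read back by [read_ratings()]; the round trip is
#' the identity on valid datasets. Labels are written in canonical lower
#' case; absent status/subtype are written as `NA`.
#'
#' @param dataset A `study_ratings` tibble (or coercible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(dataset, path) {
  dataset <- validate_ratings(dataset)
  readr::write_csv(dataset[required_columns], path, na = "NA",
                   progress = FALSE)
  invisible(path)
}

#' @export
print.study_ratings <- function(x, ...) {
  cat("<study_ratings> ", nrow(x), " ratings, ",
      length(unique(x$patient_id)), " patients, roles: ",
      paste(sort(unique(x$role)), collapse = ", "), "\n", sep = "")
  NextMethod()
}
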