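#' Construct a chest-position label
#'
#' A position label records whether a single chest-position recording was
#' interpretable (at least one audible breath cycle) and, if so, whether it
#' was normal or abnormal; abnormal labels may carry a subtype (wheeze,
#' crackle, or both). Two invariants hold: `status` is present iff the
#' recording is interpretable, and `subtype` is absent unless `status` is
#' `"abnormal"`.
#'
#' @param interpretable Logical scalar.
#' @param status `"normal"`, `"abnormal"`, or `NA` (required `NA` when
#'   `interpretable` is `FALSE`).
#' @param subtype `"wheeze"`, `"crackle"`, `"both"`, or `NA`; only allowed
#'   when `status == "abnormal"`.
#' @return A list of class `position_label` with elements `interpretable`,
#'   `status`, `subtype`.
#' @examples
#' position_label(TRUE, "abnormal", "wheeze")
#' position_label(FALSE)
#' @export
position_label <- function(interpretable, status = NA_character_,
                           subtype = NA_character_) {
  if (!is.logical(interpretable) || length(interpretable) != 1L ||
      is.na(interpretable)) {
    stop("`interpretable` must be TRUE or FALSE", call. = FALSE)
  }
  status <- tolower(as.character(status))
  subtype <- tolower(as.character(subtype))
  if (status %in% "na") status <- NA_character_
  if (subtype %in% "na") subtype <- NA_character_
  bad <- label_violation(interpretable, status, subtype)
  if (!is.na(bad)) stop(bad, call. = FALSE)
  structure(list(interpretable = interpretable, status = status,
                 subtype = subtype),
            class = "position_label")
}

# Returns NA_character_ when the (interpretable, status, subtype) triple is
# valid, otherwise a message describing the violated invariant. Vector-safe
# only for scalars; vectorised checks live in validate_ratings().
label_violation <- function(interpretable, status, subtype) {
  if (!interpretable && !is.na(status)) {
    return("status must be absent when the recording is uninterpretable")
  }
  if (interpretable && (is.na(status) || !status %in% c("normal", "abnormal"))) {
    return("interpretable recordings need status 'normal' or 'abnormal'")
  }
  if (!is.na(subtype) && !identical(status, "abnormal")) {
    return("subtype is only allowed for abnormal recordings")
  }
  if (!is.na(subtype) && !subtype %in% c("wheeze", "crackle", "both")) {
    return("subtype must be 'wheeze', 'crackle' or 'both'")
  }
  NA_character_
}

#' @export
print.position_label <- function(x, ...) {
  if (!x$interpretable) {
    cat("<position_label> uninterpretable\n")
  } else if (is.na(x$subtype)) {
    cat("<position_label>", x$status, "\n")
  } else {
    cat("<position_label>", x$status, paste0("(", x$subtype, ")"), "\n")
  }
  invisible(x)
}

# Collapse a label to the key used when judging rater agreement.
# trilevel: uninterpretable / normal / abnormal.
# full:     abnormal additionally carries its subtype.
label_key <- function(interpretable, status, subtype,
                      granularity = c("trilevel", "full")) {
  granularity <- match.arg(granularity)
  key <- ifelse(!interpretable, "uninterpretable", status)
  if (granularity == "full") {
    sub <- ifelse(is.na(subtype), "", paste0(":", subtype))
    key <- ifelse(key == "abnormal", paste0(key, sub), key)
  }
  key
}

roles <- c("primary", "arbitrator1", "arbitrator2", "ai_iteration", "clinician")
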