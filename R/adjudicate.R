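#' Adjudicate one recording through the staged listening-panel schema
#'
#' Two primary panelists rate each recording independently. If their labels
#' agree at the configured granularity, that label is final
#' (`primary_consensus`). On disagreement a first arbitrator rates the
#' recording; agreement with either primary finalises that label
#' (`arbitrator1`). If the first arbitrator agrees with neither primary, a
#' second arbitrator's label is final unconditionally (`arbitrator2`).
#'
#' Agreement is judged at `granularity = "trilevel"` by default
#' (uninterpretable / normal / abnormal): subtype disagreement between two
#' abnormal calls does not trigger arbitration, since all downstream
#' statistics are binary among interpretable recordings. `"full"` granularity
#' additionally requires subtype agreement and is provided for sensitivity
#' analyses.
#'
#' When the final status is abnormal and both contributing raters gave
#' subtypes, an identical subtype is kept and discordant subtypes are
#' recorded as `"both"` (conservative union); a single stated subtype is
#' carried through.
#'
#' @param primary_a,primary_b [position_label()]s from the two primaries.
#' @param arbitrator1,arbitrator2 [position_label()]s or `NULL`. `arbitrator1`
#'   is required whenever the primaries disagree; `arbitrator2` whenever
#'   `arbitrator1` agrees with neither primary. Superfluous arbitrator labels
#'   are ignored with a notice.
#' @param granularity `"trilevel"` (default) or `"full"`.
#' @return A list of class `final_label`: `interpretable`, `status`,
#'   `subtype`, `provenance`.
#' @export
adjudicate_position <- function(primary_a, primary_b, arbitrator1 = NULL,
                                arbitrator2 = NULL,
                                granularity = c("trilevel", "full")) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(primary_a, "position_label"),
            inherits(primary_b, "position_label"))
  key <- function(l) label_key(l$interpretable, l$status, l$subtype,
                               granularity)

  if (key(primary_a) == key(primary_b)) {
    if (!is.null(arbitrator1) || !is.null(arbitrator2)) {
      message("primaries agree; arbitrator label(s) ignored")
    }
    return(final_label(merge_labels(primary_a, primary_b),
                       "primary_consensus"))
  }
  if (is.null(arbitrator1)) {
    stop_incomplete("primaries disagree but no first arbitrator label present")
  }
  if (key(arbitrator1) == key(primary_a)) {
    if (!is.null(arbitrator2)) message("consensus reached; second arbitrator label ignored")
    return(final_label(merge_labels(arbitrator1, primary_a), "arbitrator1"))
  }
  if (key(arbitrator1) == key(primary_b)) {
    if (!is.null(arbitrator2)) message("consensus reached; second arbitrator label ignored")
    return(final_label(merge_labels(arbitrator1, primary_b), "arbitrator1"))
  }
  if (is.null(arbitrator2)) {
    stop_incomplete("first arbitrator agrees with neither primary and no second arbitrator label present")
  }
  final_label(arbitrator2, "arbitrator2")
}

stop_incomplete <- function(msg) {
  stop(structure(class = c("adjudication_incomplete", "error", "condition"),
                 list(message = msg, call = NULL)))
}

final_label <- function(label, provenance) {
  structure(list(interpretable = label$interpretable, status = label$status,
                 subtype = label$subtype, provenance = provenance),
            class = "final_label")
}

# Consensus subtype rule: identical kept, discordant -> "both", a single
# stated subtype is carried. Trilevel-agreeing labels share interpretable and
# status by construction.
merge_labels <- function(x, y) {
  sub <- NA_character_
  if (identical(x$status, "abnormal")) {
    subs <- c(x$subtype, y$subtype)
    subs <- subs[!is.na(subs)]
    if (length(subs) == 1L) sub <- subs
    if (length(subs) == 2L) sub <- if (subs[1] == subs[2]) subs[1] else "both"
  }
  list(interpretable = x$interpretable, status = x$status, subtype = sub)
}

#' @export
print.final_label <- function(x, ...) {
  lab <- if (!x$interpretable) "uninterpretable" else x$status
  if (!is.na(x$subtype)) lab <- paste0(lab, " (", x$subtype, ")")
  cat("<final_label>", lab, "via", x$provenance, "\n")
  invisible(x)
}

#' Adjudicate every recording in a study
#'
#' Applies [adjudicate_position()] to each (patient, position) that carries
#' primary-panelist ratings, consuming arbitrator ratings where present.
#'
#' @param dataset A `study_ratings` tibble (only rows with panel roles are
#'   used; other streams are ignored).
#' @param granularity Passed to [adjudicate_position()].
#' @return A tibble of class `final_labels` with one row per adjudicated
#'   recording: `patient_id`, `position`, `interpretable`, `status`,
#'   `subtype`, `provenance`.
#' @export
adjudicate_study <- function(dataset, granularity = c("trilevel", "full")) {
  granularity <- match.arg(granularity)
  dataset <- validate_ratings(dataset)

  prim <- dataset[dataset$role == "primary", ]
  if (nrow(prim) == 0L) {
    stop("no primary-panelist ratings present", call. = FALSE)
  }
  prim <- prim[order(prim$patient_id, prim$position), ]
  rec <- paste(prim$patient_id, prim$position, sep = "\r")
  counts <- rle(rec)
  if (any(counts$lengths != 2L)) {
    offender <- counts$values[which(counts$lengths != 2L)[1]]
    parts <- strsplit(offender, "\r", fixed = TRUE)[[1]]
    stop("recording ", parts[1], "/position ", parts[2], " has ",
         counts$lengths[which(counts$lengths != 2L)[1]],
         " primary rating(s); exactly 2 required", call. = FALSE)
  }
  ia <- seq(1L, nrow(prim), by = 2L)
  ib <- ia + 1L
  rec_key <- rec[ia]
  n <- length(ia)

  arb_of <- function(role) {
    arb <- dataset[dataset$role == role, ]
    idx <- match(rec_key, paste(arb$patient_id, arb$position, sep = "\r"))
    list(present = !is.na(idx),
         interpretable = arb$interpretable[idx],
         status = arb$status[idx], subtype = arb$subtype[idx])
  }
  a1 <- arb_of("arbitrator1")
  a2 <- arb_of("arbitrator2")

  ka <- label_key(prim$interpretable[ia], prim$status[ia], prim$subtype[ia],
                  granularity)
  kb <- label_key(prim$interpretable[ib], prim$status[ib], prim$subtype[ib],
                  granularity)
  need1 <- ka != kb
  if (any(need1 & !a1$present)) {
    miss <- which(need1 & !a1$present)[1]
    stop("recording ", prim$patient_id[ia[miss]], "/position ",
         prim$position[ia[miss]],
         ": primaries disagree but no first arbitrator label present",
         call. = FALSE)
  }
  k1 <- label_key(a1$interpretable, a1$status, a1$subtype, granularity)
  match_a <- need1 & a1$present & k1 == ka
  match_b <- need1 & a1$present & !match_a & k1 == kb
  need2 <- need1 & !match_a & !match_b
  if (any(need2 & !a2$present)) {
    miss <- which(need2 & !a2$present)[1]
    stop("recording ", prim$patient_id[ia[miss]], "/position ",
         prim$position[ia[miss]],
         ": first arbitrator agrees with neither primary and no second ",
         "arbitrator label present", call. = FALSE)
  }
  superfluous <- sum(a1$present & !need1) + sum(a2$present & !need2)
  if (superfluous > 0L) {
    message(superfluous, " superfluous arbitrator rating(s) ignored")
  }

  # Consensus subtype: identical kept, discordant recorded as "both", a
  # single stated subtype carried (same rule as merge_labels()).
  merge_sub <- function(status, s1, s2) {
    out <- ifelse(is.na(s1), s2, ifelse(is.na(s2), s1,
                  ifelse(s1 == s2, s1, "both")))
    ifelse(!is.na(status) & status == "abnormal", out, NA_character_)
  }

  interpretable <- prim$interpretable[ia]
  status <- prim$status[ia]
  subtype <- merge_sub(status, prim$subtype[ia], prim$subtype[ib])
  provenance <- rep("primary_consensus", n)

  w <- which(match_a)
  subtype[w] <- merge_sub(status[w], a1$subtype[w], prim$subtype[ia[w]])
  provenance[w] <- "arbitrator1"
  w <- which(match_b)
  interpretable[w] <- prim$interpretable[ib[w]]
  status[w] <- prim$status[ib[w]]
  subtype[w] <- merge_sub(status[w], a1$subtype[w], prim$subtype[ib[w]])
  provenance[w] <- "arbitrator1"
  w <- which(need2)
  interpretable[w] <- a2$interpretable[w]
  status[w] <- a2$status[w]
  subtype[w] <- ifelse(!is.na(a2$status[w]) & a2$status[w] == "abnormal",
                       a2$subtype[w], NA_character_)
  provenance[w] <- "arbitrator2"

  res <- tibble::tibble(patient_id = prim$patient_id[ia],
                        position = prim$position[ia],
                        interpretable = interpretable, status = status,
                        subtype = subtype, provenance = provenance)
  class(res) <- c("final_labels", class(res))
  res
}
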