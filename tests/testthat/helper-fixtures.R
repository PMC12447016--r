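# Deterministic fixtures built in code. The study-sized fixture mirrors the
# motivating study's published layout: 95 patients x 6 positions = 570
# recordings, 4 missing, 69 of the 566 rated uninterpretable, and the 497
# interpretable position pairs tabulating to (a=236, b=26, c=58, d=177)
# against the classifier stream.

# Pairs tibble realising given 2x2 cell counts (reference x index).
make_pairs <- function(a, b, c, d) {
  tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(a + b + c + d)),
    position = 1L,
    reference_status = rep(c("abnormal", "normal", "abnormal", "normal"),
                           c(a, b, c, d)),
    index_status = rep(c("abnormal", "abnormal", "normal", "normal"),
                       c(a, b, c, d)))
}

# Study-shaped fixture. Returns panel final labels, AI final labels, and a
# ratings table in which both primaries agree with the panel label and the
# five classifier iterations are unanimous.
study_fixture <- function() {
  pid <- sprintf("P%03d", 1:95)
  grid <- expand.grid(position = 1:6, patient_id = pid,
                      stringsAsFactors = FALSE)[, c(2, 1)]
  # 4 missing recordings: position 6 of the first four patients
  missing <- grid$patient_id %in% pid[1:4] & grid$position == 6L
  grid <- grid[!missing, ]                       # 566 rated
  # 69 uninterpretable: position 1 of patients 5..73 (each keeps >= 5
  # interpretable positions, so all 95 patients stay classifiable)
  uninterp <- grid$patient_id %in% pid[5:73] & grid$position == 1L
  stopifnot(sum(uninterp) == 69L, nrow(grid) == 566L)

  interp_idx <- which(!uninterp)                 # 497 interpretable
  panel_status <- rep(NA_character_, nrow(grid))
  ai_status <- rep("normal", nrow(grid))
  # first 294 interpretable are panel-abnormal (AI agrees on first 236);
  # of the 203 panel-normal, the first 26 are AI-abnormal
  panel_status[interp_idx] <- rep(c("abnormal", "normal"), c(294, 203))
  ai_status[interp_idx] <- rep(c("abnormal", "normal", "abnormal", "normal"),
                               c(236, 58, 26, 177))

  panel <- tibble::tibble(
    patient_id = grid$patient_id, position = as.integer(grid$position),
    interpretable = !uninterp, status = panel_status,
    subtype = NA_character_, provenance = "primary_consensus")
  ai <- tibble::tibble(
    patient_id = grid$patient_id, position = as.integer(grid$position),
    interpretable = TRUE, status = ai_status,
    subtype = NA_character_, provenance = "single_source")

  one_role <- function(rater_id, role, interpretable, status) {
    tibble::tibble(patient_id = grid$patient_id,
                   position = as.integer(grid$position),
                   rater_id = rater_id, role = role,
                   interpretable = interpretable, status = status,
                   subtype = NA_character_)
  }
  ratings <- dplyr::bind_rows(
    one_role("p1", "primary", !uninterp, panel_status),
    one_role("p2", "primary", !uninterp, panel_status),
    lapply(1:5, function(i) {
      rows <- one_role(sprintf("ai%d", i), "ai_iteration", TRUE, ai_status)
      rows[!uninterp, ]   # classifier runs on interpretable recordings only
    }))
  list(ratings = validate_ratings(ratings), panel = panel, ai = ai)
}

# Random valid position label (for property loops).
random_label <- function() {
  if (stats::runif(1) < 0.15) return(position_label(FALSE))
  st <- sample(c("normal", "abnormal"), 1)
  sub <- if (st == "abnormal" && stats::runif(1) < 0.7) {
    sample(c("wheeze", "crackle", "both"), 1)
  } else NA_character_
  position_label(TRUE, st, sub)
}

# From-definition agreement oracle: expand a 2x2 table into paired label
# vectors and recompute po and Cohen/Brennan-Prediger chance agreement by
# counting, independent of the closed-form implementation.
oracle_agreement <- function(a, b, c, d) {
  ref <- rep(c(1, 0, 1, 0), c(a, b, c, d))
  idx <- rep(c(1, 1, 0, 0), c(a, b, c, d))
  n <- length(ref)
  po <- mean(ref == idx)
  pe <- mean(ref == 1) * mean(idx == 1) + mean(ref == 0) * mean(idx == 0)
  list(po = po,
       kappa = if (pe < 1) (po - pe) / (1 - pe) else NA_real_,
       bp = (po - 0.5) / 0.5)
}
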