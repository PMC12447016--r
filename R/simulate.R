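#' Configuration for a synthetic annotation study
#'
#' Defines the generative model used by [simulate_study()]: each patient has
#' a Gaussian random effect on the log-odds of abnormality, positions are
#' abnormal independently given that effect, a fraction of recordings are
#' uninterpretable or missing, and every rater (three primary panelists, two
#' arbitrators, the classifier iterations, the bedside clinician) reports
#' the true status with its own sensitivity/specificity, independently given
#' the truth.
#'
#' Defaults emulate the magnitudes of the motivating study: 95 patients with
#' 6 chest positions, about 12% of recordings uninterpretable (69/566) and
#' 0.7% missing (4/570), about 59% of interpretable positions abnormal, a
#' classifier with sensitivity 0.80 and specificity 0.87 ensembled over 5
#' iterations, and a within-patient intra-class correlation of 0.7 on the
#' latent logistic scale (`patient_sd = 2.771`, so that
#' `patient_sd^2 / (patient_sd^2 + pi^2/3) = 0.7`;
#' `base_abnormal_logit = 0.762` then gives 59.2% marginal abnormality).
#'
#' @param n_patients Number of patients.
#' @param positions_per_patient Chest positions per patient (default 6).
#' @param base_abnormal_logit Intercept of the abnormality log-odds.
#' @param patient_sd SD of the patient random effect (>= 0).
#' @param p_uninterpretable Probability a recording is uninterpretable.
#' @param p_missing Probability a recording is missing (no rows emitted).
#' @param panelist_sens,panelist_spec Length-5 (or recycled scalar)
#'   sensitivities/specificities for the three primaries and two arbitrators,
#'   in that order.
#' @param ai_sens,ai_spec Classifier per-iteration accuracy.
#' @param ai_iterations Number of classifier iterations (default 5).
#' @param clinician_sens,clinician_spec Bedside clinician accuracy.
#' @param uncooperative_fraction Fraction of uncooperative patients.
#' @param uncooperative_agreement_or Odds ratio applied to the classifier's
#'   agreement for uncooperative patients; the classifier's error odds are
#'   divided by this (0.51 reproduces 49% lower odds of agreement).
#' @param seed Integer seed fixing the full output stream.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 95,
                              positions_per_patient = 6,
                              base_abnormal_logit = 0.762,
                              patient_sd = 2.771,
                              p_uninterpretable = 69 / 566,
                              p_missing = 4 / 570,
                              panelist_sens = 0.90,
                              panelist_spec = 0.90,
                              ai_sens = 0.80,
                              ai_spec = 0.87,
                              ai_iterations = 5,
                              clinician_sens = 0.75,
                              clinician_spec = 0.75,
                              uncooperative_fraction = 0.25,
                              uncooperative_agreement_or = 0.51,
                              seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              positions_per_patient = as.integer(positions_per_patient),
              base_abnormal_logit = base_abnormal_logit,
              patient_sd = patient_sd,
              p_uninterpretable = p_uninterpretable,
              p_missing = p_missing,
              panelist_sens = rep_len(panelist_sens, 5),
              panelist_spec = rep_len(panelist_spec, 5),
              ai_sens = ai_sens, ai_spec = ai_spec,
              ai_iterations = as.integer(ai_iterations),
              clinician_sens = clinician_sens,
              clinician_spec = clinician_spec,
              uncooperative_fraction = uncooperative_fraction,
              uncooperative_agreement_or = uncooperative_agreement_or,
              seed = as.integer(seed))
  probs <- c(cfg$p_uninterpretable, cfg$p_missing, cfg$panelist_sens,
             cfg$panelist_spec, cfg$ai_sens, cfg$ai_spec, cfg$clinician_sens,
             cfg$clinician_spec, cfg$uncooperative_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("all proportions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_patients < 1) stop("need at least one patient", call. = FALSE)
  if (cfg$positions_per_patient < 1 || cfg$positions_per_patient > 6) {
    stop("positions_per_patient must lie in 1-6", call. = FALSE)
  }
  if (cfg$ai_iterations < 1) stop("ai_iterations must be >= 1", call. = FALSE)
  if (cfg$patient_sd < 0) stop("patient_sd must be >= 0", call. = FALSE)
  if (cfg$uncooperative_agreement_or <= 0) {
    stop("uncooperative_agreement_or must be positive", call. = FALSE)
  }
  class(cfg) <- "simulation_config"
  cfg
}

subtype_levels <- c("wheeze", "crackle", "both")
subtype_probs <- c(0.4, 0.4, 0.2)

# One rater's reported status given the truth: abnormal with prob sens when
# truly abnormal, with prob 1 - spec when truly normal. Vectorised over
# recordings.
report_status <- function(true_abnormal, sens, spec) {
  p_abn <- ifelse(true_abnormal, sens, 1 - spec)
  ifelse(stats::runif(length(true_abnormal)) < p_abn, "abnormal", "normal")
}

# Inflate an error probability by dividing the agreement odds by `or`.
inflate_error <- function(e, or) {
  odds <- e / (1 - e) / or
  odds / (1 + odds)
}

#' Simulate a synthetic annotation study
#'
#' Draws a latent truth (per-patient random effect, per-position abnormal
#' status, interpretability and missingness flags), then emits imperfect
#' ratings for every stream: two of the three primary panelists chosen per
#' recording, arbitrators exactly where the adjudication schema needs them,
#' `ai_iterations` classifier calls on interpretable recordings, and one
#' bedside clinician call per recording. Uninterpretable recordings are
#' labelled uninterpretable by every panelist; the classifier and clinician
#' always return a binary status. Uncooperative patients have the
#' classifier's error odds inflated by `1 / uncooperative_agreement_or`.
#'
#' The seed expands into fixed per-stream substreams (truth, panel,
#' classifier, clinician), so adding or resizing a later stream never
#' perturbs earlier draws.
#'
#' @param config A [simulation_config()].
#' @return A list with `ratings` (a `study_ratings` tibble), `truth` (one
#'   row per non-missing recording: `patient_id`, `position`,
#'   `true_status`, `true_subtype`, `interpretable`, `cooperative`,
#'   `patient_effect`), and `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))

  # --- substream 1: latent truth ---------------------------------------
  set.seed(config$seed + 1L)
  pid <- sprintf("P%04d", seq_len(config$n_patients))
  u <- stats::rnorm(config$n_patients, 0, config$patient_sd)
  cooperative <- stats::runif(config$n_patients) >= config$uncooperative_fraction

  grid <- expand.grid(position = seq_len(config$positions_per_patient),
                      patient = seq_len(config$n_patients))
  nrec <- nrow(grid)
  p_abn <- stats::plogis(config$base_abnormal_logit + u[grid$patient])
  true_abn <- stats::runif(nrec) < p_abn
  uninterp <- stats::runif(nrec) < config$p_uninterpretable
  missing <- stats::runif(nrec) < config$p_missing
  true_sub <- sample(subtype_levels, nrec, replace = TRUE,
                     prob = subtype_probs)

  truth <- tibble::tibble(
    patient_id = pid[grid$patient], position = as.integer(grid$position),
    true_status = ifelse(true_abn, "abnormal", "normal"),
    true_subtype = ifelse(true_abn, true_sub, NA_character_),
    interpretable = !uninterp,
    cooperative = cooperative[grid$patient],
    patient_effect = u[grid$patient])[!missing, ]

  keep <- which(!missing)
  n <- length(keep)
  k_abn <- true_abn[keep]
  k_unint <- uninterp[keep]
  k_coop <- cooperative[grid$patient[keep]]
  base <- tibble::tibble(patient_id = pid[grid$patient[keep]],
                         position = as.integer(grid$position[keep]))

  rating_rows <- function(rater_id, role, status) {
    tibble::tibble(patient_id = base$patient_id, position = base$position,
                   rater_id = rater_id, role = role,
                   interpretable = TRUE, status = status,
                   subtype = NA_character_)
  }

  # --- substream 2: listening panel ------------------------------------
  set.seed(config$seed + 2L)
  omitted <- sample.int(3L, n, replace = TRUE)  # primary sitting out
  pair <- rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L))

  panel_call <- function(rater_idx) {
    status <- report_status(k_abn, config$panelist_sens[rater_idx],
                            config$panelist_spec[rater_idx])
    # abnormal calls carry a subtype: the true one when the recording is
    # truly abnormal, otherwise a fresh draw
    sub <- ifelse(status == "abnormal",
                  ifelse(k_abn, truth$true_subtype,
                         sample(subtype_levels, n, replace = TRUE,
                                prob = subtype_probs)),
                  NA_character_)
    status[k_unint] <- NA_character_
    sub[k_unint] <- NA_character_
    out <- rating_rows(sprintf("panelist%d", rater_idx),
                       if (rater_idx <= 3L) "primary"
                       else paste0("arbitrator", rater_idx - 3L),
                       status)
    out$interpretable <- !k_unint
    out$subtype <- sub
    out
  }

  # Draw all five panelists' potential calls up front (fixed draw order),
  # then keep primaries per assignment and arbitrators only where the
  # schema requires them.
  calls <- lapply(1:5, panel_call)
  prim_a_idx <- pair[omitted, 1]; prim_b_idx <- pair[omitted, 2]
  # vectorised row selection: build matrices of each column
  col_of <- function(col) {
    m <- vapply(calls[1:3], function(x) as.character(x[[col]]), character(n))
    cbind(m[cbind(seq_len(n), prim_a_idx)], m[cbind(seq_len(n), prim_b_idx)])
  }
  st <- col_of("status"); sb <- col_of("subtype"); rid <- col_of("rater_id")
  prim <- dplyr::bind_rows(
    tibble::tibble(patient_id = base$patient_id, position = base$position,
                   rater_id = rid[, 1], role = "primary",
                   interpretable = !k_unint, status = st[, 1],
                   subtype = sb[, 1]),
    tibble::tibble(patient_id = base$patient_id, position = base$position,
                   rater_id = rid[, 2], role = "primary",
                   interpretable = !k_unint, status = st[, 2],
                   subtype = sb[, 2]))

  key_a <- label_key(!k_unint, st[, 1], sb[, 1])
  key_b <- label_key(!k_unint, st[, 2], sb[, 2])
  need1 <- key_a != key_b
  arb1 <- calls[[4]][need1, ]
  key_1 <- label_key(arb1$interpretable, arb1$status, arb1$subtype)
  need2 <- which(need1)[key_1 != key_a[need1] & key_1 != key_b[need1]]
  arb2 <- calls[[5]][need2, ]

  # --- substream 3: classifier iterations ------------------------------
  set.seed(config$seed + 3L)
  ai_rows <- vector("list", config$ai_iterations)
  interp_idx <- which(!k_unint)
  e_fn <- sum(!k_unint)
  err_abn <- ifelse(k_coop[interp_idx], 1 - config$ai_sens,
                    inflate_error(1 - config$ai_sens,
                                  config$uncooperative_agreement_or))
  err_nrm <- ifelse(k_coop[interp_idx], 1 - config$ai_spec,
                    inflate_error(1 - config$ai_spec,
                                  config$uncooperative_agreement_or))
  for (it in seq_len(config$ai_iterations)) {
    p_abn_call <- ifelse(k_abn[interp_idx], 1 - err_abn, err_nrm)
    status <- ifelse(stats::runif(e_fn) < p_abn_call, "abnormal", "normal")
    ai_rows[[it]] <- tibble::tibble(
      patient_id = base$patient_id[interp_idx],
      position = base$position[interp_idx],
      rater_id = sprintf("ai%d", it), role = "ai_iteration",
      interpretable = TRUE, status = status, subtype = NA_character_)
  }

  # --- substream 4: bedside clinician ----------------------------------
  set.seed(config$seed + 4L)
  clin <- rating_rows("clinician1", "clinician",
                      report_status(k_abn, config$clinician_sens,
                                    config$clinician_spec))

  ratings <- dplyr::bind_rows(c(list(prim, arb1, arb2), ai_rows, list(clin)))
  ratings <- dplyr::arrange(ratings, .data$patient_id, .data$position,
                            .data$role, .data$rater_id)
  list(ratings = validate_ratings(ratings), truth = truth, config = config)
}

#' Expected 2x2 probability table for two imperfect raters
#'
#' Closed-form cell probabilities for a reference and an index rater that
#' are conditionally independent given a latent binary truth with the given
#' prevalence: `p11 = theta se_r se_i + (1 - theta)(1 - sp_r)(1 - sp_i)`
#' and analogously for the other cells. Serves as the analytic oracle for
#' agreement statistics computed on simulated data.
#'
#' @param prevalence Probability the truth is abnormal.
#' @param sens_ref,spec_ref Reference rater accuracy.
#' @param sens_idx,spec_idx Index rater accuracy.
#' @return A list: `p` (2x2 probability matrix, reference in rows), `po`,
#'   `pe`, `kappa` implied by the cell probabilities.
#' @examples
#' expected_table(0.5, 0.8, 0.8, 0.8, 0.8)$kappa  # 0.36
#' @export
expected_table <- function(prevalence, sens_ref, spec_ref, sens_idx,
                           spec_idx) {
  th <- prevalence
  if (any(c(th, sens_ref, spec_ref, sens_idx, spec_idx) < 0) ||
      any(c(th, sens_ref, spec_ref, sens_idx, spec_idx) > 1)) {
    stop("all arguments must be proportions in [0, 1]", call. = FALSE)
  }
  p11 <- th * sens_ref * sens_idx + (1 - th) * (1 - spec_ref) * (1 - spec_idx)
  p10 <- th * sens_ref * (1 - sens_idx) + (1 - th) * (1 - spec_ref) * spec_idx
  p01 <- th * (1 - sens_ref) * sens_idx + (1 - th) * spec_ref * (1 - spec_idx)
  p00 <- th * (1 - sens_ref) * (1 - sens_idx) + (1 - th) * spec_ref * spec_idx
  po <- p11 + p00
  ref_pos <- p11 + p10; idx_pos <- p11 + p01
  pe <- ref_pos * idx_pos + (1 - ref_pos) * (1 - idx_pos)
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  p <- matrix(c(p11, p01, p10, p00), 2, 2,
              dimnames = list(reference = c("abnormal", "normal"),
                              index = c("abnormal", "normal")))
  list(p = p, po = po, pe = pe, kappa = kappa)
}
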