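test_that("equal seeds reproduce the study byte for byte; different seeds do not", {
  cfg <- simulation_config(n_patients = 15, seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(as.data.frame(s1$ratings), as.data.frame(s2$ratings))
  expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))

  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_ratings(s1$ratings, p1); write_ratings(s2$ratings, p2)
  expect_identical(readLines(p1), readLines(p2))

  s3 <- simulate_study(simulation_config(n_patients = 15, seed = 100))
  expect_false(identical(as.data.frame(s1$ratings), as.data.frame(s3$ratings)))
})

test_that("noise-free raters drive every downstream statistic to 1", {
  cfg <- simulation_config(n_patients = 30, p_uninterpretable = 0,
                           p_missing = 0, panelist_sens = 1,
                           panelist_spec = 1, ai_sens = 1, ai_spec = 1,
                           clinician_sens = 1, clinician_spec = 1, seed = 5)
  rep <- run_pipeline(simulate_study(cfg)$ratings)
  for (cmp in c("ai_vs_panel", "clinician_vs_panel")) {
    for (lvl in c("position", "patient")) {
      blk <- rep[[cmp]][[lvl]]
      expect_equal(blk$agreement$po, 1)
      expect_equal(blk$agreement$kappa, 1)
      expect_equal(blk$agreement$bp, 1)
      expect_equal(blk$diagnostics$sens$estimate, 1)
      expect_equal(blk$diagnostics$spec$estimate, 1)
    }
  }
})

test_that("simulated truth honours the configured generative structure", {
  cfg <- simulation_config(n_patients = 50, seed = 31)
  sim <- simulate_study(cfg)
  # one row per non-missing recording, valid ratings throughout
  expect_s3_class(sim$ratings, "study_ratings")
  expect_lte(nrow(sim$truth), 50 * 6)
  # truth is never mingled into the ratings table
  expect_false(any(c("true_status", "cooperative") %in% names(sim$ratings)))
  # arbitrators appear exactly where the primaries disagree
  finals <- adjudicate_study(sim$ratings)
  expect_equal(nrow(finals), nrow(sim$truth))
})

test_that("default-config position counts match the emulated study magnitudes", {
  # Monte Carlo over seeds: interpretable positions ~ Binomial(570,
  # (1 - p_missing)(1 - p_uninterpretable)), abnormal | interpretable ~ 0.592
  n_rep <- 200
  interp <- abn <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    sim <- simulate_study(simulation_config(seed = 1000 + i))
    interp[i] <- sum(sim$truth$interpretable)
    abn[i] <- sum(sim$truth$interpretable & sim$truth$true_status == "abnormal")
  }
  expected_interp <- 570 * (1 - 4 / 570) * (1 - 69 / 566)  # 497
  se_interp <- sd(interp) / sqrt(n_rep)
  expect_lt(abs(mean(interp) - expected_interp), 4 * se_interp + 1)
  prop_abn <- sum(abn) / sum(interp)
  expect_lt(abs(prop_abn - 0.592), 0.02)
})

test_that("closed-form expected tables match hand-computed cases", {
  perfect <- expected_table(0.5, 1, 1, 1, 1)
  expect_equal(unname(diag(perfect$p)), c(0.5, 0.5))
  expect_equal(perfect$kappa, 1)

  noisy <- expected_table(0.5, 0.8, 0.8, 0.8, 0.8)
  expect_equal(noisy$po, 0.68, tolerance = 1e-12)
  expect_equal(noisy$pe, 0.5, tolerance = 1e-12)
  expect_equal(noisy$kappa, 0.36, tolerance = 1e-12)
  expect_equal(unname(noisy$p[1, 1]), 0.34, tolerance = 1e-12)

  uninformative <- expected_table(0.5, 0.9, 0.9, 0.5, 0.5)
  expect_equal(uninformative$kappa, 0, tolerance = 1e-12)
  expect_true(all(abs(rowSums(expected_table(0.3, .9, .8, .7, .6)$p) -
                      c(0.3 * 0.9 + 0.7 * 0.2, 0.3 * 0.1 + 0.7 * 0.8)) < 1e-12))
})

test_that("majority vote over five iterations beats a single iteration's sensitivity", {
  cfg5 <- simulation_config(n_patients = 400, panelist_sens = 1,
                            panelist_spec = 1, uncooperative_fraction = 0,
                            ai_iterations = 5, seed = 77)
  sim <- simulate_study(cfg5)
  panel <- adjudicate_study(sim$ratings)
  ens <- ensemble_iterations(sim$ratings)
  single <- sim$ratings[sim$ratings$role == "ai_iteration" &
                        sim$ratings$rater_id == "ai1", ]
  single <- tibble::tibble(patient_id = single$patient_id,
                           position = single$position, interpretable = TRUE,
                           status = single$status, subtype = NA_character_,
                           provenance = "single_source")
  sens_of <- function(stream) {
    metrics_from_pairs(build_comparison(panel, stream, "position"))$sens$estimate
  }
  expect_gt(sens_of(ens), sens_of(single))
})

test_that("uncooperative patients degrade the classifier as configured", {
  cfg <- simulation_config(n_patients = 600, panelist_sens = 1,
                           panelist_spec = 1, uncooperative_fraction = 0.5,
                           ai_iterations = 1, seed = 13)
  sim <- simulate_study(cfg)
  ai <- sim$ratings[sim$ratings$role == "ai_iteration", ]
  merged <- dplyr::inner_join(
    ai, sim$truth, by = c("patient_id", "position"))
  agree <- merged$status == merged$true_status
  odds <- function(x) mean(x) / (1 - mean(x))
  ratio <- odds(agree[!merged$cooperative]) / odds(agree[merged$cooperative])
  # configured agreement odds ratio 0.51; generous Monte Carlo band
  expect_lt(ratio, 0.75)
  expect_gt(ratio, 0.33)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(ai_sens = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(n_patients = 0), "at least one")
  expect_error(simulation_config(ai_iterations = 0), ">= 1")
  expect_error(simulation_config(patient_sd = -1), ">= 0")
  expect_error(simulation_config(positions_per_patient = 7), "1-6")
})
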