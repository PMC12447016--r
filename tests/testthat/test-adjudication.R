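abn <- function(sub = NA_character_) position_label(TRUE, "abnormal", sub)
nrm <- position_label(TRUE, "normal")
unint <- position_label(FALSE)

test_that("the three consensus branches resolve with the right provenance", {
  f <- adjudicate_position(abn(), abn())
  expect_equal(f$status, "abnormal")
  expect_equal(f$provenance, "primary_consensus")

  f <- adjudicate_position(abn(), nrm, arbitrator1 = nrm)
  expect_equal(f$status, "normal")
  expect_equal(f$provenance, "arbitrator1")

  f <- adjudicate_position(unint, nrm, arbitrator1 = abn(), arbitrator2 = nrm)
  expect_equal(f$status, "normal")
  expect_equal(f$provenance, "arbitrator2")
})

test_that("the second arbitrator's word is final even against all others", {
  f <- adjudicate_position(unint, nrm, arbitrator1 = abn("wheeze"),
                           arbitrator2 = abn("crackle"))
  expect_equal(f$status, "abnormal")
  expect_equal(f$subtype, "crackle")
  expect_equal(f$provenance, "arbitrator2")
})

test_that("a required arbitrator cannot be absent; a superfluous one is ignored", {
  expect_error(adjudicate_position(abn(), nrm),
               class = "adjudication_incomplete")
  expect_error(adjudicate_position(abn(), nrm, arbitrator1 = unint),
               class = "adjudication_incomplete")
  expect_message(f <- adjudicate_position(abn(), abn(), arbitrator1 = nrm),
                 "ignored")
  expect_equal(f$provenance, "primary_consensus")
})

test_that("adjudication is symmetric in the primaries and idempotent under consensus", {
  set.seed(101)
  for (i in 1:200) {
    a <- random_label(); b <- random_label()
    r1 <- random_label(); r2 <- random_label()
    f_ab <- tryCatch(
      suppressMessages(adjudicate_position(a, b, r1, r2)), error = identity)
    f_ba <- tryCatch(
      suppressMessages(adjudicate_position(b, a, r1, r2)), error = identity)
    if (inherits(f_ab, "error")) {
      expect_s3_class(f_ba, "error")
    } else {
      expect_equal(f_ab$status, f_ba$status)
      expect_equal(f_ab$interpretable, f_ba$interpretable)
    }
    # all inputs equal -> that label, by primary consensus
    f_same <- suppressMessages(adjudicate_position(a, a, a, a))
    expect_equal(f_same$provenance, "primary_consensus")
    expect_equal(f_same$status, a$status)
  }
})

test_that("the second arbitrator is reached iff the first three raters are pairwise distinct", {
  labs <- list(unint, nrm, abn())
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    a <- labs[[i]]; b <- labs[[j]]; r1 <- labs[[k]]
    res <- tryCatch(
      suppressMessages(adjudicate_position(a, b, r1, arbitrator2 = NULL)),
      error = identity)
    distinct <- length(unique(c(i, j, k))) == 3L
    if (distinct) {
      expect_s3_class(res, "adjudication_incomplete")
    } else {
      expect_s3_class(res, "final_label")
    }
  }
})

test_that("subtype disagreement alone does not arbitrate at trilevel, but does at full granularity", {
  f <- adjudicate_position(abn("wheeze"), abn("crackle"))
  expect_equal(f$provenance, "primary_consensus")
  expect_equal(f$subtype, "both")  # discordant subtypes, conservative union
  f2 <- adjudicate_position(abn("wheeze"), abn("wheeze"))
  expect_equal(f2$subtype, "wheeze")
  f3 <- adjudicate_position(abn("wheeze"), abn())
  expect_equal(f3$subtype, "wheeze")  # single stated subtype carried

  expect_error(
    adjudicate_position(abn("wheeze"), abn("crackle"), granularity = "full"),
    class = "adjudication_incomplete")
  f4 <- adjudicate_position(abn("wheeze"), abn("crackle"),
                            arbitrator1 = abn("crackle"),
                            granularity = "full")
  expect_equal(f4$provenance, "arbitrator1")
  expect_equal(f4$subtype, "crackle")
})

test_that("a fully concordant study adjudicates to all primary-consensus labels", {
  fx <- study_fixture()
  finals <- adjudicate_study(fx$ratings)
  expect_equal(nrow(finals), 566L)
  expect_true(all(finals$provenance == "primary_consensus"))
  expect_equal(sum(!finals$interpretable), 69L)
})

test_that("non-consensus provenance counts equal independently recounted primary disagreements", {
  sim <- simulate_study(simulation_config(n_patients = 40, seed = 11))
  finals <- adjudicate_study(sim$ratings)

  prim <- sim$ratings[sim$ratings$role == "primary", ]
  keys <- label_key(prim$interpretable, prim$status, prim$subtype)
  disagreements <- sum(tapply(keys, paste(prim$patient_id, prim$position),
                              function(k) k[1] != k[2]))
  expect_equal(sum(finals$provenance != "primary_consensus"), disagreements)
  expect_equal(nrow(finals), nrow(prim) / 2L)
})

test_that("a recording with other than two primary ratings is an integrity error", {
  fx <- study_fixture()
  broken <- fx$ratings[-1, ]  # drops one primary rating of P001 position 1
  expect_error(adjudicate_study(broken), "exactly 2 required")
})
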