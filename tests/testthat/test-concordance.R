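test_that("published marginals reconstruct the unique 2x2 table", {
  t <- reconstruct_table(497, 294, 262, 413)
  expect_equal(c(t$a, t$b, t$c, t$d), c(236, 26, 58, 177))
  tp <- reconstruct_table(95, 80, 82, 87)
  expect_equal(c(tp$a, tp$b, tp$c, tp$d), c(77, 5, 3, 10))
  perfect <- reconstruct_table(10, 5, 5, 10)
  expect_equal(c(perfect$a, perfect$b, perfect$c, perfect$d), c(5, 0, 0, 5))
})

test_that("inconsistent marginals are rejected", {
  expect_error(reconstruct_table(10, 5, 5, 9), "not an integer")
  expect_error(reconstruct_table(10, 9, 9, 2), "negative cell")
  expect_error(reconstruct_table(10, 11, 5, 5), "exceed n")
  expect_error(contingency_table(1, -1, 0, 0), "non-negative")
  expect_error(contingency_table(0, 0, 0, 0), "at least one")
})

test_that("reconstruction inverts the marginals it was given", {
  set.seed(303)
  for (i in 1:500) {
    a <- rpois(1, 20); b <- rpois(1, 5); c <- rpois(1, 5); d <- rpois(1, 15)
    if (a + b + c + d == 0) a <- 1
    t <- reconstruct_table(a + b + c + d, a + c, a + b, a + d)
    expect_equal(c(t$a, t$b, t$c, t$d), c(a, b, c, d))
  }
})

test_that("raw agreement is the diagonal fraction", {
  expect_equal(round(raw_agreement(contingency_table(236, 26, 58, 177)), 3),
               0.831)
  expect_equal(round(raw_agreement(contingency_table(77, 5, 3, 10)), 3),
               0.916)
  expect_equal(raw_agreement(contingency_table(0, 4, 4, 0)), 0)
})

test_that("Cohen's kappa and its interval match the published values", {
  k <- cohen_kappa(reconstruct_table(497, 294, 262, 413))
  expect_equal(round(k$kappa, 3), 0.659)
  expect_equal(round(unname(k$kappa_ci), 3), c(0.592, 0.725))
  expect_equal(cohen_kappa(reconstruct_table(95, 80, 82, 87))$kappa, 0.665,
               tolerance = 5e-4)
  expect_equal(cohen_kappa(contingency_table(10, 0, 0, 10))$kappa, 1)
  expect_error(cohen_kappa(contingency_table(5, 0, 0, 0)), "degenerate")
})

test_that("Brennan-Prediger matches the published values and its q=2 identity", {
  b <- brennan_prediger(reconstruct_table(497, 294, 262, 413))
  expect_equal(round(b$bp, 3), 0.662)
  expect_equal(round(unname(b$bp_ci), 3), c(0.596, 0.728))
  expect_equal(round(brennan_prediger(reconstruct_table(95, 80, 82, 87))$bp, 3),
               0.832)
  expect_equal(brennan_prediger(contingency_table(1, 1, 1, 1))$bp, 0)

  set.seed(404)
  for (i in 1:200) {
    cells <- rpois(4, 6); if (sum(cells) == 0) cells[1] <- 1
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    expect_identical(brennan_prediger(t)$bp, 2 * raw_agreement(t) - 1)
  }
})

test_that("kappa is transpose-symmetric and 1 exactly when off-diagonals vanish", {
  set.seed(505)
  for (i in 1:200) {
    cells <- rpois(4, 6); if (sum(cells) == 0) cells[1] <- 1
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    tt <- contingency_table(cells[1], cells[3], cells[2], cells[4])
    margins_fixed <- tryCatch(cohen_kappa(t)$kappa, error = function(e) NA)
    if (!is.na(margins_fixed)) {
      expect_equal(margins_fixed, cohen_kappa(tt)$kappa, tolerance = 1e-12)
      expect_equal(margins_fixed == 1, cells[2] == 0 && cells[3] == 0)
      expect_equal(raw_agreement(t) == 1, cells[2] == 0 && cells[3] == 0)
    }
  }
})

test_that("kappa and Brennan-Prediger match the from-definition oracle on small tables", {
  for (n in 1:8) {
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      d <- n - a - b - c
      t <- contingency_table(a, b, c, d)
      o <- oracle_agreement(a, b, c, d)
      expect_equal(raw_agreement(t), o$po, tolerance = 1e-12)
      expect_equal(brennan_prediger(t)$bp, o$bp, tolerance = 1e-12)
      if (!is.na(o$kappa)) {
        expect_equal(cohen_kappa(t)$kappa, o$kappa, tolerance = 1e-12)
      }
    }
  }
})

test_that("agreement strength bins follow the conventional categories", {
  expect_equal(classify_strength(0.659), "substantial")
  expect_equal(classify_strength(0.832), "almost perfect")
  expect_equal(classify_strength(-0.2), "poor")
  expect_equal(classify_strength(0), "poor")
  expect_equal(classify_strength(0.1), "slight")
  expect_equal(classify_strength(0.2), "fair")
  expect_equal(classify_strength(0.4), "moderate")
  expect_equal(classify_strength(1), "almost perfect")
  expect_equal(classify_strength(-1), "poor")
  expect_error(classify_strength(1.2), "\\[-1, 1\\]")
})

test_that("agreement_stats combines both statistics with their categories", {
  a <- agreement_stats(reconstruct_table(497, 294, 262, 413))
  expect_s3_class(a, "agreement_result")
  expect_equal(a$strength_kappa, "substantial")
  expect_equal(a$strength_bp, "substantial")
  expect_equal(agreement_stats(reconstruct_table(95, 80, 82, 87))$strength_bp,
               "almost perfect")
})
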