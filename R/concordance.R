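#' Construct a 2x2 agreement table
#'
#' Cross-classification of binary abnormal/normal calls by a reference and an
#' index rater: `a` both abnormal, `b` index abnormal only, `c` reference
#' abnormal only, `d` both normal.
#'
#' @param a,b,c,d Non-negative integer cell counts; `a+b+c+d >= 1`.
#' @return A list of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) < 1) stop("table must contain at least one pair", call. = FALSE)
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), n = as.numeric(a + b + c + d)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(index = c("abnormal", "normal"),
                              reference = c("abnormal", "normal")))
  cat("<contingency_table> n =", x$n, "\n")
  print(m)
  invisible(x)
}

#' Reconstruct the 2x2 table from published marginal counts
#'
#' Reports typically print the total, the number abnormal by each rater, and
#' the number of agreements, not the full table. Those four numbers determine
#' the table uniquely: `a = (reference_positive + index_positive + agreement
#' - n) / 2`, then `b`, `c`, `d` follow by subtraction. Inconsistent
#' marginals (parity failure or a negative cell) are an error.
#'
#' @param n Total pairs.
#' @param reference_positive Pairs the reference rated abnormal.
#' @param index_positive Pairs the index rated abnormal.
#' @param agreement Pairs on which the raters agreed.
#' @return A [contingency_table()].
#' @examples
#' reconstruct_table(497, 294, 262, 413)
#' @export
reconstruct_table <- function(n, reference_positive, index_positive,
                              agreement) {
  vals <- c(n, reference_positive, index_positive, agreement)
  if (any(is.na(vals)) || any(vals < 0)) {
    stop("all marginal counts must be non-negative", call. = FALSE)
  }
  if (any(c(reference_positive, index_positive, agreement) > n)) {
    stop("marginal counts cannot exceed n", call. = FALSE)
  }
  two_a <- reference_positive + index_positive + agreement - n
  if (two_a %% 2 != 0) {
    stop("inconsistent marginals: implied cell count is not an integer",
         call. = FALSE)
  }
  a <- two_a / 2
  b <- index_positive - a
  c <- reference_positive - a
  d <- agreement - a
  if (min(a, b, c, d) < 0) {
    stop("inconsistent marginals: implied negative cell count", call. = FALSE)
  }
  contingency_table(a, b, c, d)
}

#' Tabulate paired binary labels into a 2x2 table
#'
#' @param pairs A tibble with `reference_status` and `index_status`
#'   (normal/abnormal), e.g. from [build_comparison()].
#' @return A [contingency_table()].
#' @export
tabulate_pairs <- function(pairs) {
  ref <- tolower(pairs$reference_status)
  idx <- tolower(pairs$index_status)
  if (!all(c(ref, idx) %in% c("normal", "abnormal"))) {
    stop("pair statuses must be binary normal/abnormal", call. = FALSE)
  }
  contingency_table(sum(ref == "abnormal" & idx == "abnormal"),
                    sum(ref == "normal" & idx == "abnormal"),
                    sum(ref == "abnormal" & idx == "normal"),
                    sum(ref == "normal" & idx == "normal"))
}

#' Raw (observed) agreement
#'
#' @param t A [contingency_table()].
#' @return Proportion of pairs on the agreement diagonal, `(a+d)/n`.
#' @export
raw_agreement <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  (t$a + t$d) / t$n
}

#' Cohen's kappa with a large-sample confidence interval
#'
#' Chance agreement is margin-based: `pe = ((a+b)(a+c) + (c+d)(b+d)) / n^2`
#' and `kappa = (po - pe) / (1 - pe)`. The standard error uses the simple
#' large-sample form `sqrt(po (1-po) / n) / (1 - pe)`; the Wald interval is
#' clamped to [-1, 1].
#'
#' @param t A [contingency_table()].
#' @param conf Confidence level (default 0.95).
#' @return A list: `po`, `pe`, `kappa`, `kappa_se`, `kappa_ci` (lo, hi),
#'   `strength` (agreement-strength category), `n`.
#' @examples
#' cohen_kappa(reconstruct_table(497, 294, 262, 413))
#' @export
cohen_kappa <- function(t, conf = 0.95) {
  stopifnot(inherits(t, "contingency_table"))
  po <- raw_agreement(t)
  pe <- ((t$a + t$b) * (t$a + t$c) + (t$c + t$d) * (t$b + t$d)) / t$n^2
  if (pe >= 1) {
    stop("degenerate margins: both raters constant, chance agreement is 1",
         call. = FALSE)
  }
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / t$n) / (1 - pe)
  ci <- clamp_ci(kappa, se, conf)
  list(po = po, pe = pe, kappa = kappa, kappa_se = se, kappa_ci = ci,
       strength = classify_strength(kappa), n = t$n)
}

#' Brennan-Prediger chance-adjusted agreement
#'
#' Uses a fixed chance level of `1/q` for `q` categories, robust to skewed
#' margins: `bp = (po - 1/q) / (1 - 1/q)`. For the binary case this is
#' `2 po - 1`. Standard error `sqrt(po (1-po) / n) / (1 - 1/q)`, Wald
#' interval clamped to [-1, 1].
#'
#' @param t A [contingency_table()].
#' @param q Number of categories (default 2).
#' @param conf Confidence level (default 0.95).
#' @return A list: `po`, `bp`, `bp_se`, `bp_ci` (lo, hi), `strength`, `n`.
#' @examples
#' brennan_prediger(reconstruct_table(95, 80, 82, 87))
#' @export
brennan_prediger <- function(t, q = 2, conf = 0.95) {
  stopifnot(inherits(t, "contingency_table"))
  if (q < 2) stop("q must be at least 2", call. = FALSE)
  po <- raw_agreement(t)
  bp <- (po - 1 / q) / (1 - 1 / q)
  se <- sqrt(po * (1 - po) / t$n) / (1 - 1 / q)
  ci <- clamp_ci(bp, se, conf)
  list(po = po, bp = bp, bp_se = se, bp_ci = ci,
       strength = classify_strength(bp), n = t$n)
}

#' Round half away from zero
#'
#' Conventional display rounding (2.5 -> 3), as used in clinical reporting,
#' in place of R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clamp_ci <- function(point, se, conf) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(lo = max(-1, point - z * se), hi = min(1, point + z * se))
}

#' Full agreement summary for a 2x2 table
#'
#' Convenience wrapper combining [raw_agreement()], [cohen_kappa()] and
#' [brennan_prediger()] into one result object.
#'
#' @param t A [contingency_table()].
#' @param conf Confidence level.
#' @return A list of class `agreement_result` with fields `po`, `pe`,
#'   `kappa`, `kappa_se`, `kappa_ci`, `bp`, `bp_se`, `bp_ci`,
#'   `strength_kappa`, `strength_bp`, `n`.
#' @export
agreement_stats <- function(t, conf = 0.95) {
  ck <- cohen_kappa(t, conf)
  bp <- brennan_prediger(t, conf = conf)
  structure(list(po = ck$po, pe = ck$pe,
                 kappa = ck$kappa, kappa_se = ck$kappa_se,
                 kappa_ci = ck$kappa_ci,
                 bp = bp$bp, bp_se = bp$bp_se, bp_ci = bp$bp_ci,
                 strength_kappa = ck$strength, strength_bp = bp$strength,
                 n = t$n),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("<agreement_result> n =", x$n, "\n")
  cat(sprintf("  observed agreement  %.3f\n", x$po))
  cat(sprintf("  Cohen's kappa       %.3f (%.3f, %.3f)  %s\n",
              x$kappa, x$kappa_ci[1], x$kappa_ci[2], x$strength_kappa))
  cat(sprintf("  Brennan-Prediger    %.3f (%.3f, %.3f)  %s\n",
              x$bp, x$bp_ci[1], x$bp_ci[2], x$strength_bp))
  invisible(x)
}

#' Categorise agreement strength
#'
#' Bins a chance-adjusted agreement statistic into the conventional
#' categories: poor (<= 0), slight, fair, moderate, substantial, almost
#' perfect. Cut points fall midway between the category bounds on the
#' rounded scale (0.195, 0.395, 0.595, 0.795), half-open on the left.
#'
#' @param statistic A value in [-1, 1].
#' @return The category name.
#' @export
classify_strength <- function(statistic) {
  if (is.na(statistic) || statistic < -1 || statistic > 1) {
    stop("statistic must lie in [-1, 1]", call. = FALSE)
  }
  cuts <- c(-1, 0, 0.195, 0.395, 0.595, 0.795, 1)
  labels <- c("poor", "slight", "fair", "moderate", "substantial",
              "almost perfect")
  labels[findInterval(statistic, cuts, left.open = TRUE,
                      rightmost.closed = TRUE) ]
}
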