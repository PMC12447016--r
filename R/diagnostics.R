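#' Diagnostic accuracy of the index classifier against a reference standard
#'
#' From a 2x2 table (`a` true positive, `b` false positive, `c` false
#' negative, `d` true negative) computes sensitivity, specificity, positive
#' and negative predictive values (exact Clopper-Pearson binomial intervals),
#' positive and negative likelihood ratios and the diagnostic odds ratio
#' (Wald intervals on the log scale).
#'
#' Log-scale standard errors: `SE(ln LR+) = sqrt(1/a - 1/(a+c) + 1/b -
#' 1/(b+d))`, `SE(ln LR-) = sqrt(1/c - 1/(a+c) + 1/d - 1/(b+d))`,
#' `SE(ln DOR) = sqrt(1/a + 1/b + 1/c + 1/d)`.
#'
#' A ratio metric whose cells include a zero is reported as undefined
#' (`NA` with `defined = FALSE`) rather than a silent infinity; setting
#' `correction = TRUE` applies the Haldane-Anscombe 0.5 continuity
#' correction to every cell for the ratio metrics instead.
#'
#' @param t A [contingency_table()] with `a+c >= 1` and `b+d >= 1`.
#' @param conf Confidence level (default 0.95).
#' @param correction Apply the 0.5 continuity correction to ratio metrics
#'   when a cell is zero (default `FALSE`).
#' @return A list of class `diagnostic_result`. Proportion metrics `sens`,
#'   `spec`, `ppv`, `npv` are lists `(estimate, lo, hi)`; ratio metrics
#'   `lr_pos`, `lr_neg`, `dor` additionally carry `defined`.
#'   `abnormal_fraction_index` is the index-positive fraction `(a+b)/n`.
#' @examples
#' diagnostic_metrics(reconstruct_table(497, 294, 262, 413))
#' @export
diagnostic_metrics <- function(t, conf = 0.95, correction = FALSE) {
  stopifnot(inherits(t, "contingency_table"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  if (a + c < 1 || b + d < 1) {
    stop("need at least one reference-positive and one reference-negative pair",
         call. = FALSE)
  }

  prop <- function(x, m) {
    ci <- stats::binom.test(round(x), round(m), conf.level = conf)$conf.int
    list(estimate = x / m, lo = ci[1], hi = ci[2])
  }

  res <- list(
    sens = prop(a, a + c), spec = prop(d, b + d),
    ppv = if (a + b >= 1) prop(a, a + b) else list(estimate = NA_real_, lo = NA_real_, hi = NA_real_),
    npv = if (c + d >= 1) prop(d, c + d) else list(estimate = NA_real_, lo = NA_real_, hi = NA_real_))

  z <- stats::qnorm(1 - (1 - conf) / 2)
  # A ratio metric is undefined when its point estimate is not finite (a
  # zero denominator cell); an estimate of 0 is defined, but its log-scale
  # interval is not and is reported NA.
  ratio <- function(est, log_se) {
    if (!is.finite(est)) {
      return(list(estimate = NA_real_, lo = NA_real_, hi = NA_real_,
                  defined = FALSE))
    }
    if (!is.finite(log_se) || est == 0) {
      return(list(estimate = est, lo = NA_real_, hi = NA_real_,
                  defined = TRUE))
    }
    list(estimate = est, lo = exp(log(est) - z * log_se),
         hi = exp(log(est) + z * log_se), defined = TRUE)
  }

  # Continuity-corrected cells are used only for the ratio metrics, and only
  # when requested and needed.
  use_cc <- correction && min(a, b, c, d) == 0
  aa <- a + 0.5 * use_cc; bb <- b + 0.5 * use_cc
  cc <- c + 0.5 * use_cc; dd <- d + 0.5 * use_cc

  se_r <- aa / (aa + cc); sp_r <- dd / (bb + dd)
  res$lr_pos <- ratio(se_r / (1 - sp_r),
                      sqrt(1 / aa - 1 / (aa + cc) + 1 / bb - 1 / (bb + dd)))
  res$lr_neg <- ratio((1 - se_r) / sp_r,
                      sqrt(1 / cc - 1 / (aa + cc) + 1 / dd - 1 / (bb + dd)))
  res$dor <- ratio((aa * dd) / (bb * cc),
                   sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd))

  res$abnormal_fraction_index <- (a + b) / t$n
  res$table <- t
  res$conf <- conf
  class(res) <- "diagnostic_result"
  res
}

#' @export
print.diagnostic_result <- function(x, ...) {
  pct <- function(p) sprintf("%.1f (%.1f, %.1f)",
                             round_half_up(100 * p$estimate, 1),
                             round_half_up(100 * p$lo, 1),
                             round_half_up(100 * p$hi, 1))
  rat <- function(r, digits) {
    if (!isTRUE(r$defined)) return("undefined")
    sprintf(paste0("%.", digits, "f (%.", digits, "f, %.", digits, "f)"),
            round_half_up(r$estimate, digits), round_half_up(r$lo, digits),
            round_half_up(r$hi, digits))
  }
  cat("<diagnostic_result> n =", x$table$n, "\n")
  cat("  abnormal by index  ", sprintf("%.1f%%", 100 * x$abnormal_fraction_index), "\n")
  cat("  sensitivity, %     ", pct(x$sens), "\n")
  cat("  specificity, %     ", pct(x$spec), "\n")
  cat("  PPV, %             ", pct(x$ppv), "\n")
  cat("  NPV, %             ", pct(x$npv), "\n")
  cat("  LR+                ", rat(x$lr_pos, 2), "\n")
  cat("  LR-                ", rat(x$lr_neg, 2), "\n")
  cat("  diagnostic OR      ", rat(x$dor, 1), "\n")
  invisible(x)
}

#' Diagnostic metrics from paired labels
#'
#' Tabulates paired binary labels (reference, index) into a 2x2 table and
#' delegates to [diagnostic_metrics()]. Either stream — listening panel or
#' bedside clinician — may serve as the reference; the reference is whatever
#' occupies `reference_status`.
#'
#' @param pairs A tibble with `reference_status`, `index_status`.
#' @inheritParams diagnostic_metrics
#' @return A `diagnostic_result`.
#' @export
metrics_from_pairs <- function(pairs, conf = 0.95, correction = FALSE) {
  ref <- tolower(pairs$reference_status)
  if (length(unique(ref)) < 2L) {
    stop("reference has a single status; both classes required", call. = FALSE)
  }
  diagnostic_metrics(tabulate_pairs(pairs), conf = conf,
                     correction = correction)
}
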