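#' Design effect for clustered observations
#'
#' Variance inflation for observations clustered in groups of size `m` with
#' intra-class correlation `icc`: `1 + (m - 1) * icc`.
#'
#' @param m Cluster size (recordings per participant), `m >= 1`.
#' @param icc Intra-class correlation in [0, 1].
#' @return The inflation factor.
#' @examples
#' design_effect(6, 0.7)  # 4.5
#' @export
design_effect <- function(m, icc) {
  if (m < 1) stop("cluster size must be at least 1", call. = FALSE)
  if (icc < 0 || icc > 1) stop("icc must lie in [0, 1]", call. = FALSE)
  1 + (m - 1) * icc
}

#' Cluster-adjusted sample size for an agreement proportion
#'
#' Number of participants needed to estimate an agreement proportion `p`
#' with a confidence interval of half-width `halfwidth` when each
#' participant contributes a cluster of `m` recordings with intra-class
#' correlation `icc`. The unclustered normal-approximation count
#' `z^2 p (1 - p) / halfwidth^2` is inflated by the design effect and the
#' ceiling applied once, last.
#'
#' @param p Anticipated agreement proportion, 0 < p < 1.
#' @param halfwidth Absolute CI half-width, 0 < halfwidth < 1.
#' @param m Cluster size (default 1).
#' @param icc Intra-class correlation (default 0).
#' @param conf Confidence level (default 0.95).
#' @return Integer participant count.
#' @examples
#' sample_size(p = 0.7, halfwidth = 0.2, m = 6, icc = 0.7)  # 91
#' @export
sample_size <- function(p, halfwidth, m = 1, icc = 0, conf = 0.95) {
  if (p <= 0 || p >= 1) stop("p must lie strictly in (0, 1)", call. = FALSE)
  if (halfwidth <= 0 || halfwidth >= 1) {
    stop("halfwidth must lie strictly in (0, 1)", call. = FALSE)
  }
  if (conf <= 0 || conf >= 1) stop("conf must lie in (0, 1)", call. = FALSE)
  if (halfwidth >= min(p, 1 - p)) {
    warning("halfwidth >= min(p, 1 - p): the interval may cross 0 or 1",
            call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  deff <- design_effect(m, icc)
  as.integer(ceiling(deff * z^2 * p * (1 - p) / halfwidth^2))
}
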