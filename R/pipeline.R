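#' Run the full evaluation pipeline on a ratings table
#'
#' Adjudicates the listening-panel ratings through the staged consensus
#' schema, ensembles the classifier iterations by majority vote, gates on
#' panel interpretability, pairs the streams at chest-position and patient
#' level, and computes agreement (raw, Cohen's kappa, Brennan-Prediger) and
#' diagnostic accuracy at both levels with the panel as reference. If
#' clinician ratings are present, the clinician-vs-panel comparison is
#' computed the same way.
#'
#' @param ratings A `study_ratings` tibble, or a path to a ratings CSV.
#' @param granularity Agreement granularity for adjudication
#'   (`"trilevel"` or `"full"`).
#' @param tie Majority-vote tie policy (`"error"`, `"abnormal"`,
#'   `"normal"`).
#' @param conf Confidence level for all intervals.
#' @param out Optional path; when given, the report is also written as JSON.
#' @return A list of class `run_report`: per comparison (`ai_vs_panel`, and
#'   `clinician_vs_panel` when available) and per level (`position`,
#'   `patient`) the marginal counts, 2x2 table, `agreement_result` and
#'   `diagnostic_result`; plus a `provenance` block (inputs, configuration,
#'   package version) sufficient to recompute the report.
#' @export
run_pipeline <- function(ratings, granularity = c("trilevel", "full"),
                         tie = c("error", "abnormal", "normal"),
                         conf = 0.95, out = NULL) {
  granularity <- match.arg(granularity)
  tie <- match.arg(tie)
  ratings_path <- if (is.character(ratings) && length(ratings) == 1L) ratings
                  else NA_character_
  if (!is.na(ratings_path)) ratings <- read_ratings(ratings_path)
  ratings <- validate_ratings(ratings)

  panel <- adjudicate_study(ratings, granularity = granularity)
  streams <- list(ai = ensemble_iterations(ratings, tie = tie))
  if (any(ratings$role == "clinician")) {
    clin <- ratings[ratings$role == "clinician", ]
    streams$clinician <- tibble::tibble(
      patient_id = clin$patient_id, position = clin$position,
      interpretable = clin$interpretable, status = clin$status,
      subtype = clin$subtype, provenance = "single_source")
  }

  level_block <- function(pairs) {
    t <- tabulate_pairs(pairs)
    list(n = t$n,
         reference_positive = t$a + t$c,
         index_positive = t$a + t$b,
         agreement_count = t$a + t$d,
         table = t,
         agreement = agreement_stats(t, conf = conf),
         diagnostics = diagnostic_metrics(t, conf = conf))
  }

  comparisons <- lapply(streams, function(s) {
    list(position = level_block(build_comparison(panel, s, "position")),
         patient = level_block(build_comparison(panel, s, "patient")))
  })
  names(comparisons) <- paste0(names(streams), "_vs_panel")

  report <- structure(
    c(comparisons,
      list(panel_labels = panel,
           provenance = list(
             ratings_path = ratings_path,
             n_ratings = nrow(ratings),
             granularity = granularity, tie = tie, conf = conf,
             package_version = as.character(utils::packageVersion("panelagree"))))),
    class = "run_report")
  if (!is.null(out)) write_report_json(report, out)
  report
}

#' @export
print.run_report <- function(x, ...) {
  for (cmp in setdiff(names(x), c("panel_labels", "provenance"))) {
    cat("==", gsub("_", " ", cmp), "==\n")
    for (lvl in c("position", "patient")) {
      blk <- x[[cmp]][[lvl]]
      cat("--", lvl, "level (n =", blk$n, ") --\n")
      print(blk$agreement)
      print(blk$diagnostics)
    }
  }
  invisible(x)
}

# Flatten a report into JSON-serialisable structure (tables as cell lists).
write_report_json <- function(report, path) {
  simplify <- function(x) {
    if (inherits(x, "contingency_table")) {
      return(list(a = x$a, b = x$b, c = x$c, d = x$d, n = x$n))
    }
    if (inherits(x, "final_labels") || tibble::is_tibble(x)) {
      return(as.data.frame(x))
    }
    if (is.list(x)) return(lapply(unclass(x), simplify))
    x
  }
  jsonlite::write_json(simplify(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

# Marginal counts printed in the motivating study's results tables, used by
# reproduce_paper() as fixed inputs.
published_marginals <- list(
  position = list(n = 497, reference_positive = 294, index_positive = 262,
                  agreement = 413),
  patient = list(n = 95, reference_positive = 80, index_positive = 82,
                 agreement = 87))

published_display <- list(
  position = list(po_pct = 83.1, kappa = 0.659, kappa_ci = c(0.592, 0.725),
                  bp = 0.662, bp_ci = c(0.596, 0.728),
                  sens_pct = 80.3, spec_pct = 87.2, ppv_pct = 90.1,
                  npv_pct = 75.3, lr_pos = 6.27, lr_neg = 0.23, dor = 27.7),
  patient = list(po_pct = 91.6, kappa = 0.665, bp = 0.832,
                 sens_pct = 96.3, spec_pct = 66.7, ppv_pct = 93.9,
                 lr_pos = 2.89, lr_neg = 0.06, dor = 51.3))

#' Recompute the headline statistics from the published marginal counts
#'
#' Reconstructs the chest-position (n = 497) and patient (n = 95) 2x2
#' tables from the published marginal counts, recomputes every agreement
#' and diagnostic-accuracy statistic, and the design-stage sample size
#' (p = 0.7, half-width 0.2, cluster size 6, ICC 0.7), and checks each
#' against its published display value at display rounding.
#'
#' @param conf Confidence level (default 0.95).
#' @return A list of class `reproduction_report`: per level the
#'   reconstructed table, `agreement_result`, `diagnostic_result` and a
#'   `checks` tibble (statistic, computed, published, pass); plus
#'   `sample_size`.
#' @export
reproduce_paper <- function(conf = 0.95) {
  levels <- lapply(names(published_marginals), function(lvl) {
    m <- published_marginals[[lvl]]
    t <- reconstruct_table(m$n, m$reference_positive, m$index_positive,
                           m$agreement)
    agr <- agreement_stats(t, conf = conf)
    diag <- diagnostic_metrics(t, conf = conf)
    pub <- published_display[[lvl]]
    computed <- c(po_pct = round_half_up(100 * agr$po, 1),
                  kappa = round_half_up(agr$kappa, 3),
                  bp = round_half_up(agr$bp, 3),
                  sens_pct = round_half_up(100 * diag$sens$estimate, 1),
                  spec_pct = round_half_up(100 * diag$spec$estimate, 1),
                  ppv_pct = round_half_up(100 * diag$ppv$estimate, 1),
                  npv_pct = round_half_up(100 * diag$npv$estimate, 1),
                  lr_pos = round_half_up(diag$lr_pos$estimate, 2),
                  lr_neg = round_half_up(diag$lr_neg$estimate, 2),
                  dor = round_half_up(diag$dor$estimate, 1))
    scalar_pub <- pub[!vapply(pub, function(v) length(v) > 1, logical(1))]
    comp_vals <- unname(computed[names(scalar_pub)])
    pub_vals <- unname(unlist(scalar_pub))
    checks <- tibble::tibble(statistic = names(scalar_pub),
                             computed = comp_vals, published = pub_vals,
                             pass = comp_vals == pub_vals)
    if (lvl == "position") {
      ci_comp <- round_half_up(c(agr$kappa_ci, agr$bp_ci), 3)
      ci_pub <- c(pub$kappa_ci, pub$bp_ci)
      checks <- dplyr::bind_rows(checks, tibble::tibble(
        statistic = c("kappa_ci_lo", "kappa_ci_hi", "bp_ci_lo", "bp_ci_hi"),
        computed = ci_comp, published = ci_pub, pass = ci_comp == ci_pub))
    }
    list(table = t, agreement = agr, diagnostics = diag, checks = checks)
  })
  names(levels) <- names(published_marginals)
  structure(c(levels,
              list(sample_size = sample_size(p = 0.7, halfwidth = 0.2,
                                             m = 6, icc = 0.7, conf = 0.95),
                   sample_size_published = 91)),
            class = "reproduction_report")
}

#' @export
print.reproduction_report <- function(x, ...) {
  for (lvl in c("position", "patient")) {
    cat("==", lvl, "level (n =", x[[lvl]]$table$n, ") ==\n")
    print(x[[lvl]]$agreement)
    print(x[[lvl]]$diagnostics)
    ok <- x[[lvl]]$checks$pass
    cat(sprintf("  checks vs published values: %d/%d pass\n",
                sum(ok), length(ok)))
  }
  cat("sample size (p=0.7, halfwidth=0.2, m=6, icc=0.7):", x$sample_size,
      "(published", paste0(x$sample_size_published, ")"), "\n")
  invisible(x)
}
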