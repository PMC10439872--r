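# End-to-end study driver: similarity check, per-arm model fitting,
# counterfactual cross-arm prediction, indicator derivation, and
# per-patient recommendations.

#' Study configuration
#'
#' @param n_per_arm Eyes per treatment arm (default 30).
#' @param seed Master seed; sub-seeds for generation, outcome noise and
#'   cross-validation are derived from it deterministically.
#' @param config Generator configuration ([default_config()]); ignored
#'   when `cohort_le` / `cohort_lpi` are supplied.
#' @param cohort_le,cohort_lpi Optional user cohorts (treated, i.e. with
#'   `IOP_post`); when `NULL` synthetic arms are generated.
#' @param alpha Similarity-test significance (default 0.01).
#' @param gamma Outlier significance (default 0.01).
#' @param ncomp PCR components (default 2).
#' @param K Cross-validation segments (`NULL`: leave-one-out).
#' @param K_select Segments used inside the variable-selection loop
#'   (default 10).
#' @param p_level Variable-selection significance (default 0.05).
#' @param gray Gray-zone half-width, mm Hg (default 1).
#' @return A `pac_study_config` list.
#' @export
study_config <- function(n_per_arm = 30, seed = 1, config = default_config(),
                         cohort_le = NULL, cohort_lpi = NULL,
                         alpha = 0.01, gamma = 0.01, ncomp = 2,
                         K = NULL, K_select = 10, p_level = 0.05, gray = 1) {
  stopifnot(n_per_arm >= 0, alpha > 0, alpha < 1, gamma > 0, gamma < 1,
            ncomp >= 1, p_level > 0, p_level < 1, gray >= 0)
  structure(
    list(n_per_arm = n_per_arm, seed = seed, config = config,
         cohort_le = cohort_le, cohort_lpi = cohort_lpi,
         alpha = alpha, gamma = gamma, ncomp = ncomp, K = K,
         K_select = K_select, p_level = p_level, gray = gray),
    class = "pac_study_config"
  )
}

study_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1, 5)
  list(gen_le = s[1], gen_lpi = s[2], out_le = s[3], out_lpi = s[4],
       cv = s[5])
}

#' Run the full treatment-selection study
#'
#' Executes the complete workflow on synthetic (or supplied) cohorts:
#' generate / load both arms; test their similarity with DD-SIMCA in both
#' directions (a failed similarity check is recorded as a warning, not an
#' abort -- the check is diagnostic); fit the per-arm PCR models with
#' outlier screening; cross-predict each arm with the other arm's model
#' including the `+/- 3 * RMSEP` intervals; derive the full indicator and
#' reduce it to the short indicator by backward elimination; and attach a
#' recommendation for every patient. Deterministic given the config seed.
#'
#' @param cfg A [study_config()].
#' @param outdir Optional output directory; when given the report is also
#'   rendered to CSV/JSON/figure files via [report_render()].
#' @return A `pac_study` report list.
#' @export
run_study <- function(cfg = study_config(), outdir = NULL) {
  stopifnot(inherits(cfg, "pac_study_config"))
  seeds <- study_seeds(cfg$seed)
  feats <- pac_features()

  if (is.null(cfg$cohort_le)) {
    pre_le <- generate_cohort(cfg$config, cfg$n_per_arm, seeds$gen_le)
    arm_le <- simulate_outcomes(pre_le, cfg$config, "LE", seeds$out_le)
    cohort_le <- arm_le$cohort
    truth_le <- arm_le$truth
  } else {
    cohort_le <- cfg$cohort_le
    truth_le <- NULL
  }
  if (is.null(cfg$cohort_lpi)) {
    pre_lpi <- generate_cohort(cfg$config, cfg$n_per_arm, seeds$gen_lpi)
    arm_lpi <- simulate_outcomes(pre_lpi, cfg$config, "LPI", seeds$out_lpi)
    cohort_lpi <- arm_lpi$cohort
    truth_lpi <- arm_lpi$truth
  } else {
    cohort_lpi <- cfg$cohort_lpi
    truth_lpi <- NULL
  }

  sim_le <- fit_simca(cohort_le, features = feats, ncomp = cfg$ncomp,
                      alpha = cfg$alpha)
  sim_lpi <- fit_simca(cohort_lpi, features = feats, ncomp = cfg$ncomp,
                       alpha = cfg$alpha)
  similarity <- dplyr::bind_rows(
    dplyr::mutate(similarity_test(sim_le, cohort_lpi),
                  direction = "LPI vs LE model", .before = 1),
    dplyr::mutate(similarity_test(sim_lpi, cohort_le),
                  direction = "LE vs LPI model", .before = 1)
  )
  if (!all(similarity$similar)) {
    warning("the two arms failed the DD-SIMCA similarity check in at ",
            "least one direction; continuing, but the counterfactual ",
            "comparison may not be exchangeable")
  }

  data_le <- with_delta_iop(cohort_le)
  data_lpi <- with_delta_iop(cohort_lpi)
  fit_le <- fit_with_outlier_removal(
    data_le, features = feats, ncomp = cfg$ncomp, gamma = cfg$gamma,
    K = cfg$K, seed = seeds$cv)
  fit_lpi <- fit_with_outlier_removal(
    data_lpi, features = feats, ncomp = cfg$ncomp, gamma = cfg$gamma,
    K = cfg$K, seed = seeds$cv)

  counterfactual <- counterfactual_table(fit_le, fit_lpi,
                                         data_le, data_lpi)

  short <- select_short_indicator(
    data_le, data_lpi, features = feats, ncomp = cfg$ncomp,
    p_level = cfg$p_level, K = cfg$K_select, seed = seeds$cv,
    gray = cfg$gray)
  full <- short$provenance$full_indicator

  pooled <- dplyr::bind_rows(data_le, data_lpi)
  recommendations <- recommend_treatment(short, pooled)
  recommendations$arm <- pooled$arm

  report <- structure(
    list(
      config = cfg, seeds = seeds,
      cohort_le = cohort_le, cohort_lpi = cohort_lpi,
      truth_le = truth_le, truth_lpi = truth_lpi,
      similarity = similarity,
      fit_le = fit_le, fit_lpi = fit_lpi,
      counterfactual = counterfactual,
      indicator_full = full, indicator_short = short,
      recommendations = recommendations
    ),
    class = "pac_study"
  )
  if (!is.null(outdir)) report_render(report, outdir)
  report
}

#' Counterfactual cross-arm prediction table
#'
#' For every treated patient, the observed IOP reduction under the
#' received treatment next to the prediction (with `+/- 3 * RMSEP`
#' interval) the *other* arm's model makes for the same eye -- the
#' hypothetical outcome had the alternative treatment been chosen. The
#' PAS flag is echoed for interpretation: eyes with peripheral anterior
#' synechiae are expected to deviate from the model predictions.
#'
#' @param fit_le,fit_lpi Validated `pac_pcr` arm models.
#' @param data_le,data_lpi Treated cohorts with `delta_iop`.
#' @return A tibble with one row per patient: `id`, `arm`, `PAS`,
#'   `actual`, `predicted_other`, `lwr`, `upr`, `half_width`,
#'   `other_arm`.
#' @export
counterfactual_table <- function(fit_le, fit_lpi, data_le, data_lpi) {
  one <- function(data, model, other_arm) {
    if (!"delta_iop" %in% names(data)) data <- with_delta_iop(data)
    keep <- !is.na(data$delta_iop)
    if (any(!keep)) {
      warning(sum(!keep), " row(s) without IOP_post skipped in the ",
              "counterfactual table")
      data <- data[keep, , drop = FALSE]
    }
    pred <- predict_with_interval(model, data)
    tibble::tibble(
      id = data$id, arm = data$arm,
      PAS = if ("PAS" %in% names(data)) data$PAS else NA,
      actual = data$delta_iop,
      predicted_other = pred$fit, lwr = pred$lwr, upr = pred$upr,
      half_width = pred$half_width, other_arm = other_arm
    )
  }
  dplyr::bind_rows(
    one(data_lpi, fit_le, other_arm = "LE"),
    one(data_le, fit_lpi, other_arm = "LPI")
  )
}

#' Render a study report to files
#'
#' Writes the cohort, similarity, counterfactual and recommendation
#' tables as CSV, the model and indicator summaries and a manifest as
#' JSON, and the two diagnostic figures (counterfactual scatter and
#' full-vs-short indicator scatter) as PDF.
#'
#' @param report A `pac_study` report.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
report_render <- function(report, outdir) {
  stopifnot(inherits(report, "pac_study"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) {
    stop("cannot create output directory ", outdir, call. = FALSE)
  }
  path <- function(f) file.path(outdir, f)
  readr::write_csv(report$cohort_le, path("cohort_le.csv"))
  readr::write_csv(report$cohort_lpi, path("cohort_lpi.csv"))
  readr::write_csv(report$similarity, path("similarity.csv"))
  readr::write_csv(report$counterfactual, path("counterfactual.csv"))
  readr::write_csv(report$recommendations, path("recommendations.csv"))
  models <- list(
    LE = c(as.list(glance(report$fit_le)),
           list(coefficients = as.list(tidy(report$fit_le)$estimate))),
    LPI = c(as.list(glance(report$fit_lpi)),
            list(coefficients = as.list(tidy(report$fit_lpi)$estimate)))
  )
  jsonlite::write_json(models, path("models.json"), auto_unbox = TRUE,
                       digits = NA)
  inds <- list(
    full = list(intercept = report$indicator_full$intercept,
                slopes = as.list(report$indicator_full$slopes)),
    short = list(intercept = report$indicator_short$intercept,
                 slopes = as.list(report$indicator_short$slopes),
                 replacement_rmse =
                   report$indicator_short$provenance$replacement_rmse,
                 correlation_with_full =
                   report$indicator_short$provenance$correlation_with_full)
  )
  jsonlite::write_json(inds, path("indicators.json"), auto_unbox = TRUE,
                       digits = NA)
  ggplot2::ggsave(path("counterfactual.pdf"),
                  plot_counterfactual(report), width = 7, height = 5)
  ggplot2::ggsave(path("indicator_comparison.pdf"),
                  plot_indicator_comparison(report), width = 5, height = 5)
  manifest <- list(
    package = "pacsel",
    seed = report$config$seed,
    n_le = nrow(report$cohort_le),
    n_lpi = nrow(report$cohort_lpi),
    files = c("cohort_le.csv", "cohort_lpi.csv", "similarity.csv",
              "counterfactual.csv", "recommendations.csv", "models.json",
              "indicators.json", "counterfactual.pdf",
              "indicator_comparison.pdf"),
    n_recommendations = nrow(report$recommendations),
    decisions = as.list(table(report$recommendations$decision))
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Counterfactual scatter plot
#'
#' Observed IOP reduction against the other arm's prediction with
#' `+/- 3 * RMSEP` interval bars, one panel per arm; eyes with PAS are
#' marked.
#'
#' @param report A `pac_study` report (or a counterfactual table).
#' @return A ggplot.
#' @export
plot_counterfactual <- function(report) {
  tab <- if (inherits(report, "pac_study")) report$counterfactual else report
  tab <- dplyr::arrange(tab, .data$arm, .data$actual)
  tab <- dplyr::mutate(dplyr::group_by(tab, .data$arm),
                       rank = dplyr::row_number())
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                           colour = "indianred", width = 0.3, alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(y = .data$predicted_other),
                        colour = "indianred") +
    ggplot2::geom_point(ggplot2::aes(y = .data$actual, shape = .data$PAS),
                        colour = "steelblue") +
    ggplot2::facet_wrap(~ .data$arm, scales = "free_x",
                        labeller = ggplot2::as_labeller(function(a)
                          paste0(a, " arm: observed vs counterfactual"))) +
    ggplot2::labs(x = "patient (ordered by observed effect)",
                  y = "IOP reduction (mm Hg)",
                  shape = "PAS") +
    ggplot2::theme_minimal()
}

#' Full-versus-short indicator scatter
#'
#' @param report A `pac_study` report.
#' @return A ggplot with the identity line; the gray zone is shaded.
#' @export
plot_indicator_comparison <- function(report) {
  stopifnot(inherits(report, "pac_study"))
  pooled <- dplyr::bind_rows(with_delta_iop(report$cohort_le),
                             with_delta_iop(report$cohort_lpi))
  g <- report$indicator_short$gray
  d <- tibble::tibble(
    full = evaluate_indicator(report$indicator_full, pooled),
    short = evaluate_indicator(report$indicator_short, pooled)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$full, y = .data$short)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = -g, ymax = g,
                      alpha = 0.12, fill = "grey40") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "full indicator (mm Hg)",
                  y = "short indicator (mm Hg)") +
    ggplot2::theme_minimal()
}

#' @export
print.pac_study <- function(x, ...) {
  cat("Treatment-selection study report\n")
  cat(sprintf("  arms: LE n = %d, LPI n = %d\n",
              nrow(x$cohort_le), nrow(x$cohort_lpi)))
  cat(sprintf("  similarity (empirical power): %s\n",
              paste(sprintf("%s %.2f", x$similarity$direction,
                            x$similarity$empirical), collapse = "; ")))
  cat(sprintf("  LE model: RMSEC %.2f, RMSECV %.2f | LPI model: RMSEC %.2f, RMSECV %.2f\n",
              x$fit_le$rmsec, x$fit_le$rmsecv,
              x$fit_lpi$rmsec, x$fit_lpi$rmsecv))
  cat(sprintf("  short indicator: %d features, replacement RMS %.2f mm Hg\n",
              length(x$indicator_short$slopes),
              x$indicator_short$provenance$replacement_rmse))
  print(table(x$recommendations$decision))
  invisible(x)
}
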