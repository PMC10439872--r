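# Treatment-selection indicators.
#
# Equating the two arm-specific linear regressions of the IOP reduction
# yields a separating hyperplane: the full indicator
#   Ind_Full(x) = A0 + sum_i A_i x_i = yhat_LE(x) - yhat_LPI(x),
# the predicted mm Hg advantage of lens extraction over iridotomy for a
# patient with features x. Positive values favour LE, negative LPI, and
# values inside the gray zone |Ind| <= g (default g = 1 mm Hg, the
# estimation accuracy of the indicator) favour neither.

new_indicator <- function(variant, intercept, slopes, gray = 1,
                          provenance = list()) {
  structure(
    list(variant = variant, intercept = intercept, slopes = slopes,
         gray = gray, provenance = provenance),
    class = "pac_indicator"
  )
}

#' Derive the full treatment-selection indicator
#'
#' Subtracts the raw-unit coefficients of the two arm models:
#' `A0 = b0_LE - b0_LPI`, `A_i = b_i(LE) - b_i(LPI)`, so that the
#' indicator value at any x equals the difference of the two model
#' predictions exactly.
#'
#' @param fit_le,fit_lpi `pac_pcr` models for the LE and LPI arms, fitted
#'   on the same feature schema.
#' @param gray Gray-zone half-width in mm Hg (default 1).
#' @return A `pac_indicator` with `variant = "full"`.
#' @export
derive_full_indicator <- function(fit_le, fit_lpi, gray = 1) {
  stopifnot(inherits(fit_le, "pac_pcr"), inherits(fit_lpi, "pac_pcr"))
  if (!identical(names(fit_le$slopes), names(fit_lpi$slopes))) {
    stop("the two models do not share a feature schema", call. = FALSE)
  }
  new_indicator(
    "full",
    intercept = fit_le$intercept - fit_lpi$intercept,
    slopes = fit_le$slopes - fit_lpi$slopes,
    gray = gray,
    provenance = list(source = "derived",
                      rmsecv_le = fit_le$rmsecv, rmsecv_lpi = fit_lpi$rmsecv)
  )
}

#' The published short indicator
#'
#' The 4-parameter indicator with the published coefficients:
#' `Ind_Short = 16.80 - 0.28 * gender + 0.24 * IOP - 0.65 * AL - 2.36 * ACD`
#' (IOP in mm Hg, AL and ACD in mm, gender coded 0 = male / 1 = female;
#' the gender coding behind the published value is not stated in the
#' source and this convention is assumed, not verified). This indicator
#' ships as a usable reference; indicators refitted on synthetic cohorts
#' are labelled as such and will not reproduce these numbers.
#'
#' @param gray Gray-zone half-width in mm Hg (default 1).
#' @return A `pac_indicator` with `variant = "short"`.
#' @export
#' @examples
#' evaluate_indicator(published_short_indicator(),
#'   tibble::tibble(gender = 0, IOP = 25.5, AL = 23.5, ACD = 2.33))
published_short_indicator <- function(gray = 1) {
  new_indicator(
    "short",
    intercept = 16.80,
    slopes = c(gender = -0.28, IOP = 0.24, AL = -0.65, ACD = -2.36),
    gray = gray,
    provenance = list(source = "published")
  )
}

#' Evaluate an indicator on patient data
#'
#' Affine evaluation `intercept + sum(slope_i * x_i)` in mm Hg of
#' predicted LE-over-LPI advantage.
#'
#' @param indicator A `pac_indicator`.
#' @param data Data frame supplying every selected feature.
#' @return Numeric vector, one value per row.
#' @export
evaluate_indicator <- function(indicator, data) {
  stopifnot(inherits(indicator, "pac_indicator"))
  need <- names(indicator$slopes)
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("data is missing indicator feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- feature_matrix(data, need)
  drop(indicator$intercept + X %*% indicator$slopes)
}

#' @export
predict.pac_indicator <- function(object, newdata, ...) {
  evaluate_indicator(object, newdata)
}

#' Treatment recommendation from an indicator value
#'
#' `LE` when the value exceeds the gray half-width `g`, `LPI` when it is
#' below `-g`, otherwise `GRAY` (no method has a clinically resolvable
#' advantage); boundary values map to `GRAY`. The value itself is the
#' predicted mm Hg advantage of LE over LPI.
#'
#' @param value Numeric indicator value(s), mm Hg.
#' @param gray Gray-zone half-width `g >= 0` (default 1 mm Hg).
#' @return A tibble with `value` and `decision`.
#' @export
#' @examples
#' recommend(c(3, -3, 0.5))
recommend <- function(value, gray = 1) {
  stopifnot(gray >= 0)
  tibble::tibble(
    value = value,
    decision = factor(
      dplyr::case_when(value > gray ~ "LE", value < -gray ~ "LPI",
                       TRUE ~ "GRAY"),
      levels = c("LE", "LPI", "GRAY")
    )
  )
}

#' Recommend treatments for a cohort
#'
#' @param indicator A `pac_indicator`.
#' @param data Cohort rows.
#' @return A tibble `id` (when present), `value`, `decision`.
#' @export
recommend_treatment <- function(indicator, data) {
  out <- recommend(evaluate_indicator(indicator, data), indicator$gray)
  if ("id" %in% names(data)) out <- dplyr::bind_cols(
    tibble::tibble(id = data$id), out)
  out
}

#' Backward elimination of regression variables by F-tests
#'
#' Generic backward elimination of an ordinary least-squares approximation
#' of `y` by feature subsets. At each step every remaining variable is
#' tentatively removed; the removal is judged by the variance ratios
#' `F = (RMSE_reduced / RMSE_current)^2` for both the calibration RMSE and
#' the leave-one-out cross-validated RMSE (computed exactly via PRESS).
#' The variable with the smallest worst-case F is removed when both ratios
#' are below the F critical value at `p_level` with the residual degrees
#' of freedom of the two fits; elimination stops when every removal would
#' significantly inflate one of the errors.
#'
#' @param data Data frame with the candidate features.
#' @param y Response vector (e.g. full-indicator values).
#' @param features Candidate feature columns.
#' @param p_level Significance level of the F-test (default 0.05).
#' @return A list with `selected` (retained features), `coefficients`
#'   (named, including `(Intercept)`), `rmse`, `rmse_cv` and a `trace`
#'   tibble of the removal path.
#' @export
backward_select <- function(data, y, features, p_level = 0.05) {
  stopifnot(length(y) == nrow(data))
  n <- length(y)
  if (n <= length(features) + 1) {
    stop("need n > number of candidate features + 1", call. = FALSE)
  }
  ols_err <- function(feats) {
    X <- cbind(`(Intercept)` = 1,
               feature_matrix(data, feats))
    fit <- stats::lm.fit(X, y)
    e <- fit$residuals
    h <- rowSums(qr.Q(fit$qr)[, seq_len(fit$rank), drop = FALSE]^2)
    press <- e / pmax(1 - h, 1e-12)
    list(rmse = sqrt(mean(e^2)), rmse_cv = sqrt(mean(press^2)),
         df = n - fit$rank, coef = fit$coefficients)
  }
  current <- features
  cur <- ols_err(current)
  trace <- list()
  repeat {
    if (length(current) == 0) break
    if (cur$rmse < 1e-12) break # exact fit: ratios are undefined
    cand <- purrr::map(current, function(f) ols_err(setdiff(current, f)))
    f_cal <- vapply(cand, function(z) (z$rmse / cur$rmse)^2, 0)
    f_cv <- vapply(cand, function(z) (z$rmse_cv / cur$rmse_cv)^2, 0)
    f_worst <- pmax(f_cal, f_cv)
    crit <- vapply(cand, function(z) stats::qf(1 - p_level, z$df, cur$df), 0)
    ok <- f_worst < crit
    if (!any(ok)) break
    drop_i <- which.min(ifelse(ok, f_worst, Inf))
    trace[[length(trace) + 1]] <- tibble::tibble(
      removed = current[drop_i], f_cal = f_cal[drop_i],
      f_cv = f_cv[drop_i], f_crit = crit[drop_i]
    )
    current <- setdiff(current, current[drop_i])
    cur <- cand[[drop_i]]
  }
  if (length(current) == 0) {
    warning("elimination emptied the feature set; returning intercept only")
  }
  list(selected = current, coefficients = cur$coef,
       rmse = cur$rmse, rmse_cv = cur$rmse_cv,
       trace = dplyr::bind_rows(trace))
}

#' Derive the short indicator by model-based backward elimination
#'
#' Reproduces the published variable-selection procedure: the importance
#' of a variable is judged by how much the calibration (RMSEC) and
#' cross-validated (RMSECV) errors of the *two arm regression models*
#' change when the variable is removed and both models are refitted. If
#' for both arms and both error kinds the ratio
#' `F = (RMSE_without / RMSE_with)^2` stays below the F critical value at
#' `p_level` (the errors "changed slightly"), the variable is removable;
#' the least important removable variable is eliminated and the loop
#' repeats. The short indicator is then the hyperplane between the two
#' reduced models, and its fidelity is summarised by the replacement RMS
#' error and correlation against the full indicator over the pooled
#' cohort.
#'
#' @param data_le,data_lpi Treated cohorts (with `delta_iop`) for the two
#'   arms.
#' @param features Starting feature set (default all 37).
#' @param response Response column (default `"delta_iop"`).
#' @param ncomp PCR components (default 2).
#' @param p_level Significance of the F-test (default 0.05).
#' @param K Cross-validation segments used inside the selection loop
#'   (default 10; the final reported RMSECV of the reduced models uses
#'   the same K).
#' @param seed Seed for the cross-validation segment shuffling.
#' @param gray Gray-zone half-width of the returned indicator.
#' @return A `pac_indicator` with `variant = "short"`; provenance carries
#'   the reduced arm models, the elimination trace, and the replacement
#'   error and correlation versus the full indicator.
#' @export
select_short_indicator <- function(data_le, data_lpi,
                                   features = pac_features(),
                                   response = "delta_iop", ncomp = 2,
                                   p_level = 0.05, K = 10, seed = 1,
                                   gray = 1) {
  fit_arm <- function(data, feats) {
    m <- fit_pcr(data, features = feats, response = response,
                 ncomp = ncomp, validate = TRUE, K = K, seed = seed)
    m
  }
  full_le <- fit_arm(data_le, features)
  full_lpi <- fit_arm(data_lpi, features)
  full_ind <- derive_full_indicator(full_le, full_lpi, gray = gray)
  n_le <- full_le$n
  n_lpi <- full_lpi$n
  df_le <- n_le - ncomp - 1
  df_lpi <- n_lpi - ncomp - 1
  crit_le <- stats::qf(1 - p_level, df_le, df_le)
  crit_lpi <- stats::qf(1 - p_level, df_lpi, df_lpi)

  current <- features
  cur_le <- full_le
  cur_lpi <- full_lpi
  trace <- list()
  repeat {
    # keep at least ncomp features so the reduced models stay well-posed
    if (length(current) <= max(1, ncomp)) break
    # exact fits leave the F-ratios undefined; nothing to eliminate
    if (cur_le$rmsec < 1e-10 || cur_lpi$rmsec < 1e-10 ||
        cur_le$rmsecv < 1e-10 || cur_lpi$rmsecv < 1e-10) break
    errs <- purrr::map(current, function(f) {
      feats <- setdiff(current, f)
      m1 <- fit_arm(data_le, feats)
      m2 <- fit_arm(data_lpi, feats)
      list(m_le = m1, m_lpi = m2,
           f = c((m1$rmsec / cur_le$rmsec)^2,
                 (m1$rmsecv / cur_le$rmsecv)^2,
                 (m2$rmsec / cur_lpi$rmsec)^2,
                 (m2$rmsecv / cur_lpi$rmsecv)^2))
    })
    f_worst <- vapply(errs, function(z) {
      max(z$f / c(crit_le, crit_le, crit_lpi, crit_lpi))
    }, 0)
    ok <- f_worst < 1
    if (!any(ok)) break
    drop_i <- which.min(ifelse(ok, f_worst, Inf))
    trace[[length(trace) + 1]] <- tibble::tibble(
      removed = current[drop_i],
      f_rel_worst = f_worst[drop_i],
      n_left = length(current) - 1L
    )
    cur_le <- errs[[drop_i]]$m_le
    cur_lpi <- errs[[drop_i]]$m_lpi
    current <- setdiff(current, current[drop_i])
  }

  short <- derive_full_indicator(cur_le, cur_lpi, gray = gray)
  short$variant <- "short"
  pooled <- dplyr::bind_rows(data_le, data_lpi)
  v_full <- evaluate_indicator(full_ind, pooled)
  v_short <- evaluate_indicator(short, pooled)
  short$provenance <- list(
    source = "selected",
    selected = current,
    trace = dplyr::bind_rows(trace),
    model_le = cur_le, model_lpi = cur_lpi,
    replacement_rmse = sqrt(mean((v_full - v_short)^2)),
    correlation_with_full = stats::cor(v_full, v_short),
    full_indicator = full_ind
  )
  short
}

#' @export
print.pac_indicator <- function(x, ...) {
  cat(sprintf("Treatment-selection indicator (%s)\n", x$variant))
  cat(sprintf("  intercept: %.3f; %d feature slope(s)\n",
              x$intercept, length(x$slopes)))
  if (length(x$slopes) <= 8) {
    for (f in names(x$slopes)) {
      cat(sprintf("    %s: %.4f\n", f, x$slopes[[f]]))
    }
  }
  cat(sprintf("  gray zone: |value| <= %g mm Hg\n", x$gray))
  if (!is.null(x$provenance$replacement_rmse)) {
    cat(sprintf("  replacement RMS error vs full: %.3f mm Hg (r = %.3f)\n",
                x$provenance$replacement_rmse,
                x$provenance$correlation_with_full))
  }
  invisible(x)
}

#' @method tidy pac_indicator
#' @export
tidy.pac_indicator <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$slopes)),
    estimate = c(x$intercept, unname(x$slopes))
  )
}

#' @method glance pac_indicator
#' @export
glance.pac_indicator <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    n_features = length(x$slopes),
    gray = x$gray,
    replacement_rmse = x$provenance$replacement_rmse %||% NA_real_,
    correlation_with_full = x$provenance$correlation_with_full %||% NA_real_
  )
}
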