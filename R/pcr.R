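# Principal component regression of the treatment effect.
#
# X is autoscaled and y centered (but not scaled, so errors stay in
# mm Hg); the response is regressed on the first `ncomp` PCA scores and
# the fit is back-transformed to raw-unit coefficients
# yhat = b0 + sum_j b_j x_j. Calibration error is
# RMSE = sqrt(mean((y - yhat)^2)); validation error comes from a
# Procrustes cross-validation pseudo-set (see pcv_set).

#' Fit a principal component regression model
#'
#' @param data Data frame holding the predictors and the response, e.g. a
#'   treated cohort passed through [with_delta_iop()].
#' @param features Predictor columns (default [pac_features()]).
#' @param response Response column (default `"delta_iop"`, mm Hg).
#' @param ncomp Number of principal components; the packaged models use 2.
#' @param validate If `TRUE` (default) also compute the Procrustes
#'   cross-validated error RMSECV with `K` segments.
#' @param K Number of cross-validation segments; default `NULL` means
#'   leave-one-out for n <= 60 and 10 segments otherwise.
#' @param seed Seed for the segment shuffling.
#' @return A `pac_pcr` model with raw-unit coefficients, `rmsec` and
#'   (when validated) `rmsecv`.
#' @export
fit_pcr <- function(data, features = pac_features(), response = "delta_iop",
                    ncomp = 2, validate = TRUE, K = NULL, seed = 1) {
  X <- feature_matrix(data, features)
  if (!response %in% names(data)) {
    stop("response column '", response, "' not found", call. = FALSE)
  }
  y <- data[[response]]
  if (anyNA(y)) stop("response contains missing values", call. = FALSE)
  model <- pcr_core(X, y, ncomp)
  model$features <- features
  model$response <- response
  model$removed <- character()
  model$ids <- if ("id" %in% names(data)) data$id else as.character(seq_len(nrow(X)))
  if (validate) {
    model$rmsecv <- rmsecv_core(model, X, y, K = K, seed = seed)
  }
  model
}

pcr_core <- function(X, y, ncomp) {
  n <- nrow(X)
  p <- ncol(X)
  if (n <= ncomp) stop("need n > ncomp observations", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) {
    stop("constant predictor column(s): ",
         paste(colnames(X)[scl == 0], collapse = ", "), call. = FALSE)
  }
  Z <- scale(X, center = ctr, scale = scl)
  sv <- svd(Z)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (ncomp > rank) {
    stop("ncomp = ", ncomp, " exceeds the rank of the predictor matrix (",
         rank, ")", call. = FALSE)
  }
  V <- sv$v[, seq_len(ncomp), drop = FALSE]
  scores <- Z %*% V
  ybar <- mean(y)
  q <- drop(solve(crossprod(scores), crossprod(scores, y - ybar)))
  bz <- drop(V %*% q)
  slopes <- stats::setNames(bz / scl, colnames(X))
  intercept <- ybar - sum(slopes * ctr)
  fitted <- drop(intercept + X %*% slopes)
  structure(
    list(
      center = ctr, scale = scl, ybar = ybar,
      loadings = V, eigenvalues = (sv$d[seq_len(ncomp)]^2) / (n - 1),
      q = q, intercept = intercept, slopes = slopes,
      ncomp = ncomp, n = n, y = y, X = X,
      fitted = fitted,
      rmsec = sqrt(mean((y - fitted)^2)),
      rmsecv = NA_real_
    ),
    class = "pac_pcr"
  )
}

#' Predict from a PCR model
#'
#' @param object A `pac_pcr` model.
#' @param newdata Data frame (or matrix) with the model's features.
#' @param method `"coefficients"` (raw-unit affine form, default) or
#'   `"scores"` (autoscale, project, regress in latent space); the two
#'   agree to numerical precision.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.pac_pcr <- function(object, newdata,
                            method = c("coefficients", "scores"), ...) {
  method <- match.arg(method)
  X <- feature_matrix(as_feature_df(newdata), names(object$slopes))
  if (method == "coefficients") {
    drop(object$intercept + X %*% object$slopes)
  } else {
    Z <- scale(X, center = object$center, scale = object$scale)
    drop(object$ybar + (Z %*% object$loadings) %*% object$q)
  }
}

as_feature_df <- function(x) {
  if (is.matrix(x)) tibble::as_tibble(x) else x
}

#' Procrustes cross-validation pseudo-set
#'
#' Builds a pseudo-validation matrix `X_pv` of the same shape as the
#' calibration matrix such that applying the *global* calibration model to
#' `X_pv` reproduces segment-wise cross-validated predictions. Rows are
#' shuffled into K contiguous segments (seeded); for each segment a local
#' PCA/regression is fitted on the remaining rows, its loadings are
#' aligned to the global ones by an orthogonal Procrustes rotation, and
#' the held-out rows are reconstructed in the global basis with their
#' local score/regression behaviour and local orthogonal residuals.
#'
#' @param data Data frame with predictors and response, as in [fit_pcr()].
#' @param features,response,ncomp As in [fit_pcr()].
#' @param K Segment count (`NULL`: leave-one-out for n <= 60, else 10).
#' @param seed Seed for the segment shuffling.
#' @return A list with `X_pv` (matrix), `y` (aligned response) and the
#'   segment assignment, class `pac_pcv`.
#' @export
pcv_set <- function(data, features = pac_features(), response = "delta_iop",
                    ncomp = 2, K = NULL, seed = 1) {
  X <- feature_matrix(data, features)
  y <- data[[response]]
  model <- pcr_core(X, y, ncomp)
  pcv_core(model, X, y, K = K, seed = seed)
}

pcv_core <- function(model, X, y, K = NULL, seed = 1) {
  n <- nrow(X)
  if (is.null(K)) K <- if (n <= 60) n else 10
  if (K < 2) stop("need at least K = 2 segments", call. = FALSE)
  if (K < n && n < 2 * K) stop("need n >= 2K rows", call. = FALSE)
  if (K > n) K <- n
  ncomp <- model$ncomp
  Z <- scale(X, center = model$center, scale = model$scale)
  yc <- y - model$ybar
  V <- model$loadings
  q <- model$q

  set.seed(seed)
  # contiguous blocks after a seeded shuffle
  perm <- sample.int(n)
  seg <- split(perm, cut(seq_along(perm), breaks = K, labels = FALSE))

  Z_pv <- matrix(NA_real_, n, ncol(Z), dimnames = dimnames(Z))
  for (idx in seg) {
    Zk <- Z[idx, , drop = FALSE]
    Zr <- Z[-idx, , drop = FALSE]
    yr <- yc[-idx]
    svk <- svd(Zr, nu = 0, nv = ncomp)
    Vk <- svk$v
    # orthogonal Procrustes rotation of the local basis onto the global
    sv2 <- svd(crossprod(Vk, V))
    Rot <- sv2$u %*% t(sv2$v)
    Vk <- Vk %*% Rot
    Tr <- Zr %*% Vk
    qk <- drop(solve(crossprod(Tr), crossprod(Tr, yr)))
    Tk <- Zk %*% Vk
    ratio <- ifelse(abs(q) > 1e-12, qk / q, 1)
    T_pv <- sweep(Tk, 2, ratio, `*`)
    E_k <- Zk - Tk %*% t(Vk)
    # keep only the part of the local residual orthogonal to the global
    # basis, so the global model's prediction on the pseudo-set equals the
    # segment-wise cross-validated prediction exactly
    E_k <- E_k - (E_k %*% V) %*% t(V)
    Z_pv[idx, ] <- T_pv %*% t(V) + E_k
  }
  X_pv <- sweep(sweep(Z_pv, 2, model$scale, `*`), 2, model$center, `+`)
  structure(list(X_pv = X_pv, y = y, segments = seg, K = K, ncomp = ncomp),
            class = "pac_pcv")
}

#' Cross-validated error of a PCR model
#'
#' RMSE of the calibration model's predictions on the Procrustes
#' pseudo-validation set built from its own training data.
#'
#' @param model A `pac_pcr` model.
#' @param K,seed As in [pcv_set()].
#' @return The RMSECV (mm Hg).
#' @export
rmsecv <- function(model, K = NULL, seed = 1) {
  stopifnot(inherits(model, "pac_pcr"))
  rmsecv_core(model, model$X, model$y, K = K, seed = seed)
}

rmsecv_core <- function(model, X, y, K = NULL, seed = 1) {
  pv <- pcv_core(model, X, y, K = K, seed = seed)
  pred <- drop(model$intercept + pv$X_pv %*% model$slopes)
  sqrt(mean((y - pred)^2))
}

#' Fit a PCR model with DD-SIMCA outlier screening
#'
#' Iterates fit / flag / drop: a DD-SIMCA model is fitted to the current
#' predictor matrix, objects beyond the multiplicity-corrected outlier
#' threshold are removed, and the regression is refitted, until no flags
#' remain or `max_iter` rounds have run. Aborts if more than 20% of the
#' rows would be dropped.
#'
#' @inheritParams fit_pcr
#' @param gamma Outlier significance (default 0.01).
#' @param max_iter Maximum removal rounds (default 3).
#' @return A `pac_pcr` model; removed row ids are in `$removed`.
#' @export
fit_with_outlier_removal <- function(data, features = pac_features(),
                                     response = "delta_iop", ncomp = 2,
                                     gamma = 0.01, max_iter = 3,
                                     K = NULL, seed = 1) {
  keep <- data
  removed <- character()
  n0 <- nrow(data)
  for (iter in seq_len(max_iter)) {
    # training-distance scaling: the screened objects are the training set
    sm <- fit_simca(keep, features = features, ncomp = ncomp, alpha = gamma,
                    dof = "training")
    flags <- detect_outliers(sm, keep, gamma = gamma)$outlier
    if (!any(flags)) break
    ids <- if ("id" %in% names(keep)) keep$id[flags] else
      as.character(which(flags))
    removed <- c(removed, ids)
    if ((n0 - (nrow(keep) - sum(flags))) > 0.2 * n0) {
      stop("outlier removal would drop more than 20% of the rows; ",
           "the data look degenerate", call. = FALSE)
    }
    keep <- keep[!flags, , drop = FALSE]
  }
  model <- fit_pcr(keep, features = features, response = response,
                   ncomp = ncomp, K = K, seed = seed)
  model$removed <- removed
  model
}

#' Predict with a tolerance interval
#'
#' Point prediction with the `+/- 3 * RMSEP` interval used when reporting
#' counterfactual outcomes; the prediction error RMSEP is taken to be the
#' model's cross-validated error RMSECV.
#'
#' @param model A validated `pac_pcr` model (with `rmsecv` set).
#' @param newdata Data for prediction.
#' @return A tibble with `fit`, `lwr`, `upr`, `half_width`.
#' @export
predict_with_interval <- function(model, newdata) {
  if (!is.finite(model$rmsecv)) {
    stop("model has no RMSECV; fit with validate = TRUE or call rmsecv()",
         call. = FALSE)
  }
  fit <- predict(model, newdata)
  hw <- 3 * model$rmsecv
  tibble::tibble(fit = fit, lwr = fit - hw, upr = fit + hw,
                 half_width = hw)
}

#' @export
print.pac_pcr <- function(x, ...) {
  cat("Principal component regression\n")
  cat(sprintf("  n = %d, p = %d, components = %d\n",
              x$n, length(x$slopes), x$ncomp))
  cat(sprintf("  RMSEC = %.3f, RMSECV = %s (mm Hg)\n", x$rmsec,
              if (is.finite(x$rmsecv)) sprintf("%.3f", x$rmsecv) else "-"))
  if (length(x$removed) > 0) {
    cat("  removed outliers:", paste(x$removed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy pac_pcr
#' @export
tidy.pac_pcr <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$slopes)),
    estimate = c(x$intercept, unname(x$slopes))
  )
}

#' @method glance pac_pcr
#' @export
glance.pac_pcr <- function(x, ...) {
  tibble::tibble(
    n = x$n, ncomp = x$ncomp, rmsec = x$rmsec, rmsecv = x$rmsecv,
    n_removed = length(x$removed)
  )
}

#' @method augment pac_pcr
#' @export
augment.pac_pcr <- function(x, ...) {
  tibble::tibble(id = x$ids, observed = x$y, fitted = x$fitted,
                 residual = x$y - x$fitted)
}

#' @importFrom generics augment
#' @export
generics::augment
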