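# Data-driven SIMCA (soft independent modelling of class analogies).
#
# A PCA model of the autoscaled training class defines two distances per
# object: the score distance h (Mahalanobis distance inside the principal
# subspace) and the orthogonal distance v (residual sum of squares). Both
# are treated as scaled chi-squared variables whose scale factors (h0, v0)
# and degrees of freedom (N_h, N_v) are estimated from the training set by
# the classical method of moments, N = 2 * mean^2 / var. The total
# distance c = N_h * h / h0 + N_v * v / v0 is approximately chi-squared
# with N_h + N_v degrees of freedom, giving the acceptance region
# c <= qchisq(1 - alpha, N_h + N_v).

moment_dof <- function(x) {
  m <- mean(x)
  v <- stats::var(x)
  if (!is.finite(v) || v <= .Machine$double.eps * m^2) {
    return(list(scale = m, dof = NA_real_))
  }
  list(scale = m, dof = max(1, 2 * m^2 / v))
}

#' Fit a DD-SIMCA one-class model
#'
#' Autoscales the training data, extracts `ncomp` principal components by
#' singular value decomposition, computes per-object score and orthogonal
#' distances, and calibrates their chi-squared scaling by the method of
#' moments. Degrees of freedom are kept as positive reals (floored at 1);
#' rounding them loses calibration at small n.
#'
#' @param data Data frame (or matrix) of training objects.
#' @param features Columns to use; defaults to all numeric columns (for a
#'   cohort, pass [pac_features()]).
#' @param ncomp Number of principal components (default 2).
#' @param alpha Significance level of the acceptance region (default 0.01).
#' @param dof How to obtain the per-object distances that feed the moment
#'   estimator: `"loo"` (default) uses leave-one-out distances, so the
#'   scale factors describe the distance law of *new* objects -- essential
#'   when the variable count rivals the object count and training
#'   distances understate new-object distances; `"training"` uses the
#'   training distances directly (adequate for n >> p).
#' @return A `pac_simca` model.
#' @export
fit_simca <- function(data, features = NULL, ncomp = 2, alpha = 0.01,
                      dof = c("loo", "training")) {
  dof <- match.arg(dof)
  X <- simca_matrix(data, features)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= ncomp + 1) {
    stop("need more than ncomp + 1 = ", ncomp + 1,
         " objects to fit a SIMCA model", call. = FALSE)
  }
  if (ncomp < 1 || ncomp >= min(n, p)) {
    stop("ncomp must be in [1, min(n, p) - 1]", call. = FALSE)
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  keep <- scl > 0
  if (!all(keep)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
    ctr <- ctr[keep]
    scl <- scl[keep]
    p <- ncol(X)
  }
  Z <- scale(X, center = ctr, scale = scl)
  sv <- svd(Z, nu = 0, nv = ncomp)
  V <- sv$v
  lambda <- (sv$d[seq_len(ncomp)]^2) / (n - 1)
  scores <- Z %*% V
  h <- drop((scores^2) %*% (1 / lambda))
  v <- rowSums((Z - scores %*% t(V))^2)

  if (dof == "loo" && n >= ncomp + 3) {
    hv <- vapply(seq_len(n), function(i) {
      Xi <- X[-i, , drop = FALSE]
      ci <- colMeans(Xi)
      si <- apply(Xi, 2, stats::sd)
      si[si == 0] <- 1
      Zi <- scale(Xi, center = ci, scale = si)
      svi <- svd(Zi, nu = 0, nv = ncomp)
      Vi <- svi$v
      li <- (svi$d[seq_len(ncomp)]^2) / (n - 2)
      zo <- (X[i, ] - ci) / si
      ti <- drop(zo %*% Vi)
      c(sum(ti^2 / li), sum((zo - drop(Vi %*% ti))^2))
    }, c(0, 0))
    mh <- moment_dof(hv[1, ])
    mv <- moment_dof(hv[2, ])
  } else {
    mh <- moment_dof(h)
    mv <- moment_dof(v)
  }
  degenerate_v <- !is.finite(mv$dof) || mv$scale <= 1e-12
  if (degenerate_v) {
    warning("orthogonal variance is (near) zero; ",
            "acceptance uses the score distance only")
  }
  dof_total <- mh$dof + if (degenerate_v) 0 else mv$dof
  model <- structure(
    list(
      features = colnames(X), center = ctr, scale = scl,
      loadings = V, eigenvalues = lambda, ncomp = ncomp, alpha = alpha,
      h0 = mh$scale, N_h = mh$dof,
      v0 = if (degenerate_v) NA_real_ else mv$scale,
      N_v = if (degenerate_v) NA_real_ else mv$dof,
      degenerate_v = degenerate_v,
      c_crit = stats::qchisq(1 - alpha, dof_total),
      dof_total = dof_total,
      n_train = n
    ),
    class = "pac_simca"
  )
  model$training <- simca_distances(model, X)
  model
}

simca_matrix <- function(data, features) {
  if (is.matrix(data)) {
    X <- data
    cn <- colnames(X)
    if (is.null(cn)) cn <- rep("", ncol(X))
    cn[cn == ""] <- paste0("V", which(cn == ""))
    colnames(X) <- cn
    if (!is.null(features)) X <- X[, features, drop = FALSE]
  } else {
    if (is.null(features)) {
      features <- names(data)[vapply(data, is.numeric, TRUE)]
      features <- setdiff(features, cohort_meta_cols())
    }
    X <- feature_matrix(data, features)
  }
  X
}

#' Distances of objects under a DD-SIMCA model
#'
#' @param model A `pac_simca` model.
#' @param data New objects (data frame or matrix with the model's columns).
#' @return A tibble with per-object score distance `h`, orthogonal distance
#'   `v`, total distance `c` and the `accepted` flag at the model's alpha.
#' @export
simca_distances <- function(model, data) {
  X <- simca_matrix(data, model$features)
  if (nrow(X) == 0) stop("no objects to project", call. = FALSE)
  Z <- scale(X, center = model$center, scale = model$scale)
  scores <- Z %*% model$loadings
  h <- drop((scores^2) %*% (1 / model$eigenvalues))
  v <- rowSums((Z - scores %*% t(model$loadings))^2)
  cval <- model$N_h * h / model$h0 +
    if (model$degenerate_v) 0 else model$N_v * v / model$v0
  tibble::tibble(h = h, v = v, c = cval, accepted = cval <= model$c_crit)
}

#' Test whether a group is similar to the modelled class
#'
#' Projects a test group into a fitted DD-SIMCA model and reports the
#' empirical power (fraction of accepted objects) and a theoretical power:
#' the model-based acceptance probability of the test group, obtained by
#' moment-fitting a scaled chi-squared law to the test group's total
#' distances and evaluating it at the training critical value. The
#' similarity decision compares the accepted count against the binomial
#' fluctuation expected for a genuinely similar group (at least
#' `qbinom(0.025, m, 1 - alpha)` acceptances).
#'
#' For the symmetric test, call this twice with the roles of the two
#' groups swapped.
#'
#' @param model A `pac_simca` model fitted to the reference group.
#' @param data The test group.
#' @return A `pac_similarity` tibble row: `empirical`, `theoretical`,
#'   `n_test`, `n_accepted`, `similar`.
#' @export
similarity_test <- function(model, data) {
  d <- simca_distances(model, data)
  m <- nrow(d)
  emp <- mean(d$accepted)
  fit <- moment_dof(d$c)
  theo <- if (!is.finite(fit$dof) || fit$scale <= 0) {
    as.numeric(fit$scale <= model$c_crit)
  } else {
    stats::pchisq(model$c_crit * fit$dof / fit$scale, fit$dof)
  }
  out <- tibble::tibble(
    empirical = emp,
    theoretical = theo,
    n_test = m,
    n_accepted = sum(d$accepted),
    similar = sum(d$accepted) >=
      stats::qbinom(0.025, m, 1 - model$alpha)
  )
  class(out) <- c("pac_similarity", class(out))
  attr(out, "distances") <- d
  out
}

#' Flag outliers under a DD-SIMCA model
#'
#' An object is an outlier when its total distance exceeds the chi-squared
#' quantile at level `(1 - gamma)^(1/n)` with `N_h + N_v` degrees of
#' freedom -- the "extreme plot" convention that corrects the per-object
#' level for multiple testing across the n objects screened. To resist
#' masking, each object is judged against chi-squared scale factors
#' moment-estimated from the *other* screened objects' distances: a gross
#' outlier cannot inflate the scale it is compared with.
#'
#' @param model A `pac_simca` model.
#' @param data Objects to screen (typically the model's own training data).
#' @param gamma Outlier significance (default 0.01).
#' @return A tibble with the distances plus an `outlier` flag.
#' @export
detect_outliers <- function(model, data, gamma = 0.01) {
  d <- simca_distances(model, data)
  n <- nrow(d)
  if (n < 3) return(dplyr::mutate(d, outlier = FALSE))
  excl_moments <- function(x, i) {
    xi <- x[-i]
    m <- mean(xi)
    v <- stats::var(xi)
    if (!is.finite(v) || v <= .Machine$double.eps * m^2 || m <= 1e-12) {
      return(c(scale = m, dof = NA_real_))
    }
    c(scale = m, dof = max(1, 2 * m^2 / v))
  }
  flag <- vapply(seq_len(n), function(i) {
    mh <- excl_moments(d$h, i)
    mv <- if (model$degenerate_v) c(scale = NA, dof = NA) else
      excl_moments(d$v, i)
    use_v <- is.finite(mv["dof"])
    dof <- mh["dof"] + if (use_v) mv["dof"] else 0
    if (!is.finite(dof)) return(FALSE)
    ci <- mh["dof"] * d$h[i] / mh["scale"] +
      if (use_v) mv["dof"] * d$v[i] / mv["scale"] else 0
    unname(ci > stats::qchisq((1 - gamma)^(1 / n), dof))
  }, TRUE)
  dplyr::mutate(d, outlier = flag)
}

#' @export
print.pac_simca <- function(x, ...) {
  cat("DD-SIMCA one-class model\n")
  cat(sprintf("  objects: %d, variables: %d, components: %d\n",
              x$n_train, length(x$features), x$ncomp))
  cat(sprintf("  N_h = %.2f (h0 = %.3f), N_v = %s (v0 = %s)\n",
              x$N_h, x$h0,
              if (x$degenerate_v) "degenerate" else sprintf("%.2f", x$N_v),
              if (x$degenerate_v) "-" else sprintf("%.3f", x$v0)))
  cat(sprintf("  alpha = %g, c_crit = %.2f (chi-squared, %.2f dof)\n",
              x$alpha, x$c_crit, x$dof_total))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy pac_simca
#' @export
tidy.pac_simca <- function(x, ...) x$training

#' @method glance pac_simca
#' @export
glance.pac_simca <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train, n_features = length(x$features),
    ncomp = x$ncomp, alpha = x$alpha,
    N_h = x$N_h, h0 = x$h0, N_v = x$N_v, v0 = x$v0, c_crit = x$c_crit,
    train_acceptance = mean(x$training$accepted)
  )
}

#' Acceptance-plot of a DD-SIMCA model
#'
#' Plots objects in log-scaled (h/h0, v/v0) coordinates with the
#' acceptance boundary of the model.
#'
#' @param object A `pac_simca` model.
#' @param data Optional new objects to overlay (plotted as test points).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pac_simca
#' @export
autoplot.pac_simca <- function(object, data = NULL, ...) {
  tr <- dplyr::mutate(object$training, set = "training")
  pts <- if (!is.null(data)) {
    dplyr::bind_rows(tr, dplyr::mutate(simca_distances(object, data),
                                       set = "test"))
  } else tr
  pts <- dplyr::mutate(pts, hs = .data$h / object$h0,
                       vs = if (object$degenerate_v) 0
                            else .data$v / object$v0)
  hmax <- max(pts$hs) * 1.1
  bh <- seq(1e-4, min(hmax, object$c_crit / object$N_h),
            length.out = 200)
  boundary <- if (!object$degenerate_v) {
    tibble::tibble(
      hs = bh,
      vs = pmax(0, (object$c_crit - object$N_h * bh) / object$N_v)
    )
  } else NULL
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = log1p(.data$hs),
                                         y = log1p(.data$vs))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$set,
                                     shape = .data$accepted)) +
    ggplot2::labs(x = "log(1 + h/h0)", y = "log(1 + v/v0)",
                  colour = NULL, shape = "accepted") +
    ggplot2::theme_minimal()
  if (!is.null(boundary)) {
    p <- p + ggplot2::geom_path(
      data = dplyr::mutate(boundary, set = NA, accepted = NA),
      linetype = "dashed", colour = "grey40"
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
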