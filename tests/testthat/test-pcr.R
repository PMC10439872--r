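test_that("an exact univariate linear relation is fitted perfectly", {
  d <- tibble::tibble(x = c(1, 2, 3, 4, 5), y = 2 * c(1, 2, 3, 4, 5))
  m <- fit_pcr(d, features = "x", response = "y", ncomp = 1,
               validate = FALSE)
  expect_equal(m$rmsec, 0, tolerance = 1e-10)
  expect_equal(unname(m$slopes["x"]), 2, tolerance = 1e-10)
})

test_that("full-rank PCR equals ordinary least squares", {
  d <- toy_linear(12, 5, slopes = c(1.5, -2, 0.5), noise_sd = 0.3, seed = 2)
  m <- fit_pcr(d, features = paste0("x", 1:5), response = "y", ncomp = 5,
               validate = FALSE)
  # oracle: normal equations
  A <- cbind(1, as.matrix(d[, paste0("x", 1:5)]))
  beta <- solve(crossprod(A), crossprod(A, d$y))
  pred_ols <- drop(A %*% beta)
  expect_equal(unname(predict(m, d)), pred_ols, tolerance = 1e-8)
  expect_equal(unname(c(m$intercept, m$slopes)), unname(drop(beta)),
               tolerance = 1e-8)
})

test_that("latent-path and raw-coefficient predictions agree", {
  cfg <- default_config()
  co <- with_delta_iop(
    simulate_outcomes(generate_cohort(cfg, 30, 51), cfg, "LE", 52)$cohort)
  m <- fit_pcr(co, ncomp = 2, validate = FALSE)
  newdata <- generate_cohort(cfg, 20, seed = 53)
  expect_equal(predict(m, newdata, method = "coefficients"),
               predict(m, newdata, method = "scores"), tolerance = 1e-8)
})

test_that("RMSEC is non-increasing in the component count", {
  d <- toy_linear(25, 8, slopes = c(1, -1, 0.5, 0.2), noise_sd = 0.5,
                  seed = 3)
  errs <- vapply(1:8, function(a) {
    fit_pcr(d, features = paste0("x", 1:8), response = "y", ncomp = a,
            validate = FALSE)$rmsec
  }, 0)
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("predictions are invariant under affine rescaling of a column", {
  d <- toy_linear(20, 4, slopes = c(1, 2), noise_sd = 0.2, seed = 4)
  m1 <- fit_pcr(d, features = paste0("x", 1:4), response = "y", ncomp = 2,
                validate = FALSE)
  d2 <- d
  d2$x3 <- d2$x3 * 250 + 7
  m2 <- fit_pcr(d2, features = paste0("x", 1:4), response = "y", ncomp = 2,
                validate = FALSE)
  expect_equal(predict(m1, d), predict(m2, d2), tolerance = 1e-8)
})

test_that("degenerate fits are rejected with clear errors", {
  d <- toy_linear(6, 3, slopes = 1, seed = 5)
  expect_error(fit_pcr(d, features = paste0("x", 1:3), response = "y",
                       ncomp = 4, validate = FALSE), "rank|ncomp")
  d$x2 <- d$x1 # rank deficiency
  expect_error(fit_pcr(d, features = paste0("x", 1:3), response = "y",
                       ncomp = 3, validate = FALSE), "rank")
  expect_error(fit_pcr(d[1:2, ], features = paste0("x", 1:3),
                       response = "y", ncomp = 2, validate = FALSE),
               "n > ncomp")
})

test_that("noise-free exact-rank data give a vanishing RMSECV", {
  # y is an exact function of a rank-2 X
  set.seed(6)
  n <- 24
  t_true <- matrix(rnorm(n * 2), n, 2)
  W <- matrix(rnorm(2 * 6), 2, 6)
  X <- t_true %*% W
  colnames(X) <- paste0("x", 1:6)
  d <- tibble::as_tibble(X)
  d$y <- drop(t_true %*% c(2, -1))
  m <- fit_pcr(d, features = paste0("x", 1:6), response = "y", ncomp = 2,
               validate = TRUE, K = 8, seed = 6)
  expect_lt(m$rmsec, 1e-8)
  expect_lt(m$rmsecv, 1e-6)
})

test_that("Procrustes cross-validation tracks classical K-fold CV", {
  # oracle: explicit K-fold cross-validation with full refits
  set.seed(7)
  n <- 60; p <- 10; K <- 10
  d <- toy_linear(n, p, slopes = c(2, -1.5, 1, 0.5), noise_sd = 1, seed = 7)
  feats <- paste0("x", 1:p)
  m <- fit_pcr(d, features = feats, response = "y", ncomp = 2,
               validate = TRUE, K = K, seed = 8)
  set.seed(8)
  fold <- sample(rep(1:K, length.out = n))
  press <- 0
  for (k in 1:K) {
    mk <- fit_pcr(d[fold != k, ], features = feats, response = "y",
                  ncomp = 2, validate = FALSE)
    press <- press + sum((d$y[fold == k] - predict(mk, d[fold == k, ]))^2)
  }
  cv_classic <- sqrt(press / n)
  expect_lt(abs(m$rmsecv - cv_classic) / cv_classic, 0.15)
})

test_that("the RMSE formula averages squared residuals over all I rows", {
  # residuals all equal to 1 by construction: y = fit + 1 pattern around a
  # response orthogonal to x
  set.seed(9)
  d <- tibble::tibble(x = rnorm(20))
  d$y <- 1 + rep(c(-1, 1), 10)
  m <- fit_pcr(d[order(d$x), ], features = "x", response = "y", ncomp = 1,
               validate = FALSE)
  resid <- m$y - m$fitted
  expect_equal(m$rmsec, sqrt(mean(resid^2)), tolerance = 1e-12)
  expect_error(pcv_set(d, features = "x", response = "y", ncomp = 1, K = 1),
               "K = 2")
})

test_that("outlier screening removes a planted point and then converges", {
  cfg <- default_config()
  co <- with_delta_iop(
    simulate_outcomes(generate_cohort(cfg, 40, 61), cfg, "LE", 62)$cohort)
  m0 <- fit_pcr(co, ncomp = 2, K = 10, seed = 1)
  clean <- fit_with_outlier_removal(co, ncomp = 2, K = 10, seed = 1)
  if (length(clean$removed) == 0) {
    expect_equal(clean$rmsec, m0$rmsec, tolerance = 1e-10)
  }
  spoiled <- co
  spoiled[13, pac_features()] <-
    as.list(as.numeric(spoiled[13, pac_features()]) +
              10 * vapply(co[pac_features()], sd, 0))
  m1 <- fit_pcr(spoiled, ncomp = 2, validate = FALSE)
  m2 <- fit_with_outlier_removal(spoiled, ncomp = 2, K = 10, seed = 1)
  expect_true(spoiled$id[13] %in% m2$removed)
  expect_lt(m2$rmsec, m1$rmsec) # refit oracle: dropping it helps
  # idempotence: screening the cleaned data removes nothing more
  kept <- spoiled[!spoiled$id %in% m2$removed, ]
  m3 <- fit_with_outlier_removal(kept, ncomp = 2, K = 10, seed = 1)
  expect_equal(length(m3$removed), 0)
})

test_that("prediction intervals are +/- 3 RMSEP wide", {
  cfg <- default_config()
  co <- with_delta_iop(
    simulate_outcomes(generate_cohort(cfg, 30, 71), cfg, "LPI", 72)$cohort)
  m <- fit_pcr(co, ncomp = 2, validate = FALSE)
  expect_error(predict_with_interval(m, co), "RMSECV")
  m$rmsecv <- 0.87
  pi <- predict_with_interval(m, co)
  expect_equal(unique(pi$half_width), 3 * 0.87)
  expect_equal(pi$upr - pi$fit, rep(2.61, 30))
})

test_that("tolerance intervals cover the true expected effect", {
  cfg <- default_config()
  train <- with_delta_iop(
    simulate_outcomes(generate_cohort(cfg, 30, 81), cfg, "LE", 82)$cohort)
  m <- fit_pcr(train, ncomp = 2, K = NULL, seed = 1)
  new <- generate_cohort(cfg, 1000, seed = 83)
  truth <- simulate_outcomes(new, cfg, "LE", seed = 84)$truth$mu_le
  pi <- predict_with_interval(m, new)
  expect_gte(mean(truth >= pi$lwr & truth <= pi$upr), 0.99)
})
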