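test_that("score and orthogonal distances match a brute-force oracle", {
  # 5 objects, 2 variables, 1 component: h and v computed by hand from the
  # correlation-matrix eigendecomposition.
  X <- matrix(c(1.0, 2.1, 3.2, 4.0, 5.3,
                0.9, 2.2, 2.9, 4.3, 5.0), ncol = 2)
  colnames(X) <- c("a", "b")
  m <- fit_simca(X, ncomp = 1, alpha = 0.05, dof = "training")
  Z <- scale(X)
  eg <- eigen(cor(X), symmetric = TRUE)
  t1 <- drop(Z %*% eg$vectors[, 1])
  h_oracle <- t1^2 / eg$values[1]
  v_oracle <- rowSums((Z - t1 %*% t(eg$vectors[, 1]))^2)
  d <- simca_distances(m, X)
  expect_equal(d$h, h_oracle, tolerance = 1e-10)
  expect_equal(d$v, v_oracle, tolerance = 1e-10)
})

test_that("autoscaling makes distances invariant to column rescaling", {
  set.seed(31)
  X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, letters[1:4]))
  m1 <- fit_simca(X, ncomp = 2)
  X2 <- X
  X2[, 2] <- X2[, 2] * 1000
  m2 <- fit_simca(X2, ncomp = 2)
  d1 <- simca_distances(m1, X)
  d2 <- simca_distances(m2, X2)
  expect_equal(d1$c, d2$c, tolerance = 1e-8)
  o1 <- detect_outliers(m1, X)$outlier
  o2 <- detect_outliers(m2, X2)$outlier
  expect_identical(o1, o2)
})

test_that("training acceptance is calibrated to 1 - alpha", {
  set.seed(32)
  X <- matrix(rnorm(200 * 6), 200, 6)
  m <- fit_simca(X, ncomp = 2, alpha = 0.01)
  expect_gte(mean(m$training$accepted), 0.95)
  # large-n: acceptance within 0.01 of 1 - alpha
  X2 <- matrix(rnorm(2000 * 5), 2000, 5)
  m2 <- fit_simca(X2, ncomp = 2, alpha = 0.05)
  expect_lt(abs(mean(m2$training$accepted) - 0.95), 0.01)
})

test_that("the moment estimator recovers chi-squared degrees of freedom", {
  set.seed(33)
  for (k in c(1, 3, 10)) {
    x <- rchisq(1e4, df = k)
    est <- pacsel:::moment_dof(x)
    expect_lt(abs(est$dof - k) / k, 0.15)
  }
})

test_that("insufficient data and constant columns are handled", {
  X <- matrix(rnorm(6), 3, 2)
  expect_error(fit_simca(X, ncomp = 2), "objects")
  set.seed(34)
  Xc <- cbind(matrix(rnorm(40 * 3), 40, 3), const = 1)
  expect_warning(m <- fit_simca(Xc, ncomp = 2), "constant")
  expect_equal(length(m$features), 3)
})

test_that("a strongly shifted group is rejected", {
  set.seed(35)
  X <- matrix(rnorm(100 * 5), 100, 5)
  m <- fit_simca(X, ncomp = 2, alpha = 0.01)
  shifted <- X + 5 # +5 training SDs on every column
  st <- similarity_test(m, shifted)
  expect_lte(st$empirical, 0.1)
  expect_false(st$similar)
  # oracle: the total distances are far beyond the critical value
  expect_gt(median(simca_distances(m, shifted)$c), m$c_crit)
})

test_that("a group is similar to itself", {
  set.seed(36)
  X <- matrix(rnorm(80 * 6), 80, 6)
  m <- fit_simca(X, ncomp = 2, alpha = 0.01)
  st <- similarity_test(m, X)
  expect_gte(st$empirical, 0.95)
  expect_true(st$similar)
  expect_true(all(st$empirical <= 1, st$theoretical <= 1,
                  st$theoretical >= 0))
})

test_that("cohorts from a common generator pass the similarity test", {
  cfg <- default_config()
  emp <- vapply(1:10, function(s) {
    a <- generate_cohort(cfg, 30, seed = 300 + s)
    b <- generate_cohort(cfg, 30, seed = 400 + s)
    m <- fit_simca(a, features = pac_features(), ncomp = 2, alpha = 0.01)
    similarity_test(m, b)$empirical
  }, 0)
  expect_gte(median(emp), 0.95)
})

test_that("a planted gross outlier is flagged, clean data barely", {
  set.seed(37)
  X <- matrix(rnorm(100 * 5), 100, 5)
  X[17, ] <- 10 # 10 SDs out on every variable
  # training-distance scaling, as used when screening the training set
  m <- fit_simca(X, ncomp = 2, dof = "training")
  fl <- detect_outliers(m, X, gamma = 0.01)
  expect_true(fl$outlier[17])
  expect_lte(sum(fl$outlier), 2)
  # oracle: its total distance exceeds the multiplicity-corrected cutoff
  thr <- qchisq((1 - 0.01)^(1 / 100), m$dof_total)
  expect_gt(simca_distances(m, X)$c[17], thr)
})
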