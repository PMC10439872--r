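make_fake_pcr <- function(intercept, slopes) {
  # minimal pac_pcr skeleton with known raw-unit coefficients
  structure(list(intercept = intercept, slopes = slopes,
                 rmsec = 0.5, rmsecv = 0.6),
            class = "pac_pcr")
}

test_that("the full indicator is the coefficient difference of the arms", {
  m_le <- make_fake_pcr(1, c(x1 = 2, x2 = 0))
  m_lpi <- make_fake_pcr(0.5, c(x1 = 0, x2 = 1))
  ind <- derive_full_indicator(m_le, m_lpi)
  expect_equal(ind$intercept, 0.5)
  expect_equal(ind$slopes, c(x1 = 2, x2 = -1))
  d <- tibble::tibble(x1 = c(0, 1, 2), x2 = c(0, 1, -1))
  expect_equal(evaluate_indicator(ind, d), c(0.5, 1.5, 5.5))
})

test_that("identical arm models give a null indicator and all-gray calls", {
  m <- make_fake_pcr(2, c(a = 1, b = -3))
  ind <- derive_full_indicator(m, m)
  d <- tibble::tibble(a = rnorm(10), b = rnorm(10))
  v <- evaluate_indicator(ind, d)
  expect_equal(v, rep(0, 10))
  expect_true(all(recommend(v)$decision == "GRAY"))
  mismatch <- make_fake_pcr(2, c(a = 1, c = 0))
  expect_error(derive_full_indicator(m, mismatch), "schema")
})

test_that("indicator evaluation equals the prediction difference exactly", {
  cfg <- default_config()
  le <- with_delta_iop(
    simulate_outcomes(generate_cohort(cfg, 30, 91), cfg, "LE", 92)$cohort)
  lpi <- with_delta_iop(
    simulate_outcomes(generate_cohort(cfg, 30, 93), cfg, "LPI", 94)$cohort)
  m_le <- fit_pcr(le, ncomp = 2, validate = FALSE)
  m_lpi <- fit_pcr(lpi, ncomp = 2, validate = FALSE)
  ind <- derive_full_indicator(m_le, m_lpi)
  new <- generate_cohort(cfg, 50, seed = 95)
  expect_equal(evaluate_indicator(ind, new),
               predict(m_le, new) - predict(m_lpi, new), tolerance = 1e-8)
  # antisymmetry: swapping the models negates the indicator
  rev <- derive_full_indicator(m_lpi, m_le)
  expect_equal(evaluate_indicator(rev, new),
               -evaluate_indicator(ind, new), tolerance = 1e-10)
  dec <- recommend(evaluate_indicator(ind, new))$decision
  dec_rev <- recommend(evaluate_indicator(rev, new))$decision
  expect_equal(dec == "LE", dec_rev == "LPI")
})

test_that("noise-free exact models recover the generator truth indicator", {
  # with a flat true surface the fitted models are exact, so the derived
  # indicator must match the generator truth everywhere
  cfg <- constant_surface_config(delta_le = 8, delta_lpi = 5)
  le <- with_delta_iop(
    simulate_outcomes(generate_cohort(cfg, 30, 96), cfg, "LE", 97)$cohort)
  lpi <- with_delta_iop(
    simulate_outcomes(generate_cohort(cfg, 30, 98), cfg, "LPI", 99)$cohort)
  ind <- derive_full_indicator(fit_pcr(le, ncomp = 2, validate = FALSE),
                               fit_pcr(lpi, ncomp = 2, validate = FALSE))
  new <- generate_cohort(cfg, 40, seed = 100)
  truth <- simulate_outcomes(new, cfg, "alternate", seed = 101)$truth
  expect_equal(evaluate_indicator(ind, new), truth$indicator,
               tolerance = 1e-6)
})

test_that("the published short indicator evaluates as printed", {
  ind <- published_short_indicator()
  zero <- tibble::tibble(gender = 0, IOP = 0, AL = 0, ACD = 0)
  expect_equal(evaluate_indicator(ind, zero), 16.80)
  # 16.80 + 0.24 * 25.5 - 0.65 * 23.5 - 2.36 * 2.33, by hand: 2.15
  x <- tibble::tibble(gender = 0, IOP = 25.5, AL = 23.5, ACD = 2.33)
  expect_equal(evaluate_indicator(ind, x), 2.15, tolerance = 0.005)
  expect_error(
    evaluate_indicator(ind, tibble::tibble(gender = 0, IOP = 25, AL = 23)),
    "ACD")
})

test_that("recommendations follow the gray-zone rule", {
  r <- recommend(c(3, -3, 0.5, 1, -1, 0), gray = 1)
  expect_equal(as.character(r$decision),
               c("LE", "LPI", "GRAY", "GRAY", "GRAY", "GRAY"))
  expect_equal(r$value[1], 3) # the value is the mm Hg advantage of LE
  # enlarging the gray zone affects only the decision, not the value
  r2 <- recommend(c(3, -3, 0.5), gray = 2)
  expect_equal(r2$value, c(3, -3, 0.5))
  expect_equal(as.character(r2$decision), c("LE", "LPI", "GRAY"))
  expect_error(recommend(1, gray = -1))
})

test_that("backward elimination recovers a planted 4-variable support", {
  # target built from exactly 4 of 10 correlated candidates + small noise
  set.seed(40)
  n <- 200
  d <- toy_linear(n, 10, slopes = c(2, -1.5, 1, 0.8), noise_sd = 0.3,
                  seed = 40)
  sel <- backward_select(d, d$y, paste0("x", 1:10), p_level = 0.05)
  expect_true(all(paste0("x", 1:4) %in% sel$selected))
  expect_lte(length(sel$selected), 6)
  expect_lt(sel$rmse, 0.5)
})

test_that("the only informative variable survives elimination", {
  set.seed(41)
  d <- toy_linear(60, 1, slopes = 3, noise_sd = 0.2, seed = 41)
  sel <- backward_select(d, d$y, "x1")
  expect_equal(sel$selected, "x1")
})

test_that("model-based selection yields a faithful short indicator", {
  cfg <- default_config()
  fit_one <- function(s) {
    le <- with_delta_iop(simulate_outcomes(
      generate_cohort(cfg, 30, 110 + s), cfg, "LE", 120 + s)$cohort)
    lpi <- with_delta_iop(simulate_outcomes(
      generate_cohort(cfg, 30, 130 + s), cfg, "LPI", 140 + s)$cohort)
    list(sh = select_short_indicator(le, lpi, K = 10, seed = s),
         pooled = dplyr::bind_rows(le, lpi))
  }
  first <- fit_one(1)
  sh <- first$sh
  expect_s3_class(sh, "pac_indicator")
  expect_equal(sh$variant, "short")
  expect_lt(length(sh$slopes), 37)
  # the reported replacement error is the RMS difference of the two
  # indicators over the pooled cohort
  v_f <- evaluate_indicator(sh$provenance$full_indicator, first$pooled)
  v_s <- evaluate_indicator(sh, first$pooled)
  expect_equal(sh$provenance$replacement_rmse,
               sqrt(mean((v_f - v_s)^2)), tolerance = 1e-10)
  # the short indicator tracks the full one (median over seeds)
  cors <- vapply(1:5, function(s) {
    p <- if (s == 1) first else fit_one(s)
    p$sh$provenance$correlation_with_full
  }, 0)
  expect_gte(median(cors), 0.5)
})
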