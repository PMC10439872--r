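# Fixtures built in code; nothing is read from disk.

# A tiny treated cohort with deterministic content.
tiny_cohort <- function(n = 3) {
  cfg <- default_config()
  pre <- generate_cohort(cfg, n, seed = 42)
  simulate_outcomes(pre, cfg, "LE", seed = 43)$cohort
}

# Toy regression data: y exactly linear in a few of p correlated columns.
toy_linear <- function(n, p, slopes, noise_sd = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- numeric(p)
  beta[seq_along(slopes)] <- slopes
  y <- drop(X %*% beta) + rnorm(n, sd = noise_sd)
  d <- tibble::as_tibble(X)
  d$y <- y
  d
}

# A generator configuration with a constant response surface (all slopes
# and noise zero): every model fit is exact and counterfactuals equal the
# generator truth.
constant_surface_config <- function(delta_le = 7.33, delta_lpi = 4.87) {
  cfg <- default_config()
  for (arm in c("LE", "LPI")) {
    cfg$response[[arm]]$slopes[] <- 0
    cfg$response[[arm]]$sigma <- 0
    cfg$response[[arm]]$intercept <-
      if (arm == "LE") delta_le else delta_lpi
  }
  cfg
}
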