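test_that("a noise-free linear sample is recovered exactly", {
  set.seed(1)
  base <- runif(40, 1, 8)
  s <- tibble::tibble(country_id = rep(sprintf("C%d", 1:8), each = 5),
                      base_year = rep(seq(1950, 1970, 5), 8),
                      base_fertility = base,
                      ratio = -0.02 - 0.05 * base, delta_edu = 1)
  class(s) <- c("conv_sample", class(tibble::tibble()))
  f <- fit_convergence(s, fixed_effects = FALSE)
  expect_equal(f$beta, -0.05, tolerance = 1e-12)
  expect_equal(f$alpha, -0.02, tolerance = 1e-12)
  f2 <- fit_convergence(s, fixed_effects = TRUE)
  expect_equal(f2$beta, -0.05, tolerance = 1e-10)
})

test_that("within-transform fit matches the LSDV + explicit-sandwich oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    s <- random_sample(sample(3:8, 1), sample(2:6, 1), seed = seed * 31,
                       covariate = seed %% 2 == 0)
    cov <- if (seed %% 2 == 0) "cpr" else NULL
    a <- fit_convergence(s, fixed_effects = TRUE, covariates = cov)
    b <- lsdv_oracle(s, covariates = cov)
    expect_equal(a$beta, b$beta, tolerance = 1e-10)
    expect_equal(a$se, b$se, tolerance = 1e-10)
    expect_equal(a$ci_low, b$ci_low, tolerance = 1e-10)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-10)
  }
})

test_that("cluster sandwich matches the established implementation", {
  skip_if_not_installed("sandwich")
  s <- random_sample(8, 6, seed = 99)
  # pooled model with intercept
  m <- stats::lm(ratio ~ base_fertility, data = s)
  X <- cbind(1, s$base_fertility)
  V_pkg <- cluster_vcov(X, stats::residuals(m), s$country_id, n_params = 2)
  V_ref <- sandwich::vcovCL(m, cluster = s$country_id, type = "HC1",
                            cadjust = TRUE)
  expect_equal(unname(V_pkg), unname(V_ref), tolerance = 1e-10)

  # LSDV model: full-dummy design, same CR1 convention
  m2 <- stats::lm(ratio ~ 0 + factor(country_id) + base_fertility, data = s)
  V_ref2 <- sandwich::vcovCL(m2, cluster = s$country_id, type = "HC1",
                             cadjust = TRUE)
  f <- fit_convergence(s, fixed_effects = TRUE)
  expect_equal(f$se, sqrt(V_ref2["base_fertility", "base_fertility"]),
               tolerance = 1e-10)
})

test_that("singleton clusters reduce the sandwich to HC1", {
  skip_if_not_installed("sandwich")
  set.seed(4)
  n <- 30
  x <- runif(n); y <- 1 - 0.5 * x + rnorm(n, 0, 0.2)
  m <- stats::lm(y ~ x)
  V <- cluster_vcov(cbind(1, x), stats::residuals(m), seq_len(n), n_params = 2)
  expect_equal(unname(V), unname(sandwich::vcovHC(m, type = "HC1")),
               tolerance = 1e-10)
})

test_that("duplicating observations within clusters changes only the CR1 factor", {
  s <- random_sample(2, 6, seed = 21)
  f1 <- fit_convergence(s, fixed_effects = FALSE)
  s2 <- dplyr::bind_rows(tibble::as_tibble(s), tibble::as_tibble(s))
  class(s2) <- class(s)
  f2 <- fit_convergence(s2, fixed_effects = FALSE)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-12)
  N <- nrow(s); K <- 2
  factor_ratio <- sqrt(((2 * N - 1) / (2 * N - K)) / ((N - 1) / (N - K)))
  expect_equal(f2$se, f1$se * factor_ratio, tolerance = 1e-10)
})

test_that("clustered variance approaches the classical one under iid errors", {
  set.seed(1234)
  G <- 1500; n_per <- 3
  id <- rep(seq_len(G), each = n_per)
  x <- rnorm(G * n_per)
  y <- 2 + 0.5 * x + rnorm(G * n_per)
  m <- stats::lm(y ~ x)
  V <- cluster_vcov(cbind(1, x), stats::residuals(m), id, n_params = 2)
  classical <- stats::vcov(m)
  expect_lt(abs(sqrt(V[2, 2]) / sqrt(classical[2, 2]) - 1), 0.05)
})

test_that("degenerate designs raise identification and inference errors", {
  # base fertility constant within every country, FE on: zero within variance
  s <- random_sample(4, 3, seed = 5)
  s$base_fertility <- rep(c(2, 3, 4, 5), each = 3)
  expect_error(fit_convergence(s, fixed_effects = TRUE),
               class = "fc_identification_error")
  # a single cluster cannot support clustered inference
  s1 <- random_sample(4, 4, seed = 6)
  s1$country_id <- "only"
  expect_error(fit_convergence(s1, fixed_effects = FALSE),
               class = "fc_inference_error")
  expect_error(cluster_vcov(cbind(1, 1:4), rnorm(4), rep("a", 4)),
               class = "fc_inference_error")
})

test_that("one-country LSDV equals the per-country OLS slope", {
  s <- random_sample(1, 8, seed = 9)
  m <- stats::lm(ratio ~ base_fertility, data = s)
  # slope identification does not need clusters; inference does
  expect_error(lsdv_oracle(s), class = "fc_inference_error")
  sd2 <- random_sample(2, 8, seed = 9)
  a <- lsdv_oracle(sd2)
  b <- fit_convergence(sd2, fixed_effects = TRUE)
  expect_equal(a$beta, b$beta, tolerance = 1e-10)
})

test_that("orthogonal covariates leave the slope essentially unchanged", {
  s <- random_sample(6, 30, seed = 17)
  set.seed(18)
  z <- rnorm(nrow(s))
  # project out base_fertility so the covariate is exactly orthogonal in-sample
  z <- stats::residuals(stats::lm(z ~ s$base_fertility))
  s$orth <- z - mean(z)
  a <- fit_convergence(s, fixed_effects = FALSE)
  b <- fit_convergence(s, fixed_effects = FALSE, covariates = "orth")
  expect_equal(a$beta, b$beta, tolerance = 1e-8)
})

test_that("the convergence flag follows the sign and the interval", {
  s <- random_sample(10, 6, seed = 30, beta = -0.05)
  expect_equal(fit_convergence(s, fixed_effects = FALSE)$converged_flag,
               "convergence")
  sp <- random_sample(10, 6, seed = 31, beta = 0.05)
  expect_equal(fit_convergence(sp, fixed_effects = FALSE)$converged_flag,
               "divergence")
  # pure noise: interval covers zero
  sn <- random_sample(10, 6, seed = 32, beta = 0)
  sn$ratio <- rnorm(nrow(sn), 0, 1)
  expect_equal(fit_convergence(sn, fixed_effects = FALSE)$converged_flag,
               "null")
})

test_that("standardized slopes are invariant to affine indicator rescaling", {
  s <- random_sample(8, 6, seed = 41)
  z1 <- standardize_sample(trim_outliers(s))
  f1 <- fit_convergence(z1, fixed_effects = TRUE)
  s2 <- s
  s2$base_fertility <- 2.2 * s$base_fertility - 3
  s2$ratio <- 0.4 * s$ratio + 1
  z2 <- standardize_sample(trim_outliers(s2))
  f2 <- fit_convergence(z2, fixed_effects = TRUE)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$se, f2$se, tolerance = 1e-10)
})

test_that("fits serialize to flat rows and JSON", {
  s <- random_sample(5, 5, seed = 50)
  f <- fit_convergence(s, fixed_effects = TRUE)
  row <- as.data.frame(f)
  expect_equal(nrow(row), 1)
  expect_equal(row$beta, f$beta)
  js <- jsonlite::fromJSON(fit_to_json(f))
  expect_equal(js$beta, f$beta)
  expect_equal(js$n_countries, 5)
})
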