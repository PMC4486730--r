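test_that("noiseless data pin the simple regression at the exact line", {
  d <- tibble::tibble(x = seq_len(20), y = 1 + 2 * seq_len(20))
  f <- suppressWarnings(
    fit_simple(d, x, y, chains = 2, iter = 400, burn = 400, thin = 2,
               seed = 1)
  )
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "beta0"], 1, tolerance = 1e-2)
  expect_equal(td$estimate[td$term == "beta1"], 2, tolerance = 1e-3)
  # error variance collapses toward the lower end of its prior support
  expect_lt(td$estimate[td$term == "sigma2"], 1e-6)
})

test_that("simple-fit posterior matches least squares and covers the truth", {
  d <- make_regression("simple", list(beta0 = -18, beta1 = 0.9, sigma = 3),
                       n = 14, seed = 7)
  f <- fit_simple(d, x, y, chains = 3, iter = 1500, burn = 800, thin = 4,
                  seed = 3)
  td <- tidy(f)
  ols <- coef(lm(y ~ x, data = d))
  # Monte Carlo standard error from lag-1-based effective sample size
  for (i in 1:2) {
    v <- f$draws[[td$term[i]]]
    r <- max(0, cor(v[-1], v[-length(v)]))
    mcse <- sd(v) / sqrt(length(v) * (1 - r) / (1 + r))
    expect_lt(abs(td$estimate[i] - ols[i]), 2 * mcse)
  }
  expect_true(td$conf.low[td$term == "beta0"] < -18 &
                -18 < td$conf.high[td$term == "beta0"])
  expect_true(td$conf.low[td$term == "beta1"] < 0.9 &
                0.9 < td$conf.high[td$term == "beta1"])
})

test_that("slope and intercept are negatively correlated for positive x", {
  d <- make_regression("simple", list(beta0 = 2, beta1 = 1.5, sigma = 1,
                                      x_range = c(2, 10)), n = 25, seed = 9)
  f <- fit_simple(d, x, y, chains = 2, iter = 800, burn = 500, thin = 3,
                  seed = 4)
  expect_lt(posterior_correlations(f)["beta0", "beta1"], -0.5)
})

test_that("degenerate predictors are rejected", {
  d <- tibble::tibble(x = rep(2, 10), y = rnorm(10))
  expect_error(fit_simple(d, x, y), class = "pinnicomp_identifiability_error")
  expect_error(fit_simple(tibble::tibble(x = 1:2, y = 1:2), x, y),
               class = "pinnicomp_domain_error")
})

test_that("shared-slope fit recovers one slope and per-site intercepts", {
  d <- make_regression("shared_slope", list(
    slope = 0.9,
    intercepts = c(pelvis = 1.2, umbilicus = 0.9, mid = 0.85,
                   sternum = 0.84, axilla = 0.83, neck = 0.54),
    sigma = 0.05, x_range = c(1, 8)), n = 6, seed = 5)
  f <- fit_shared_slope(d, x, y, site, chains = 2, iter = 700, burn = 500,
                        thin = 3, seed = 5)
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "slope"], 0.9, tolerance = 0.05)
  expect_equal(td$estimate[td$term == "b_pelvis"], 1.2, tolerance = 0.2)
  expect_equal(td$estimate[td$term == "b_neck"], 0.54, tolerance = 0.2)
  # site intercepts anti-correlate with the shared slope
  expect_lt(posterior_correlations(f)["slope", "b_pelvis"], 0)
})

test_that("shared-slope fit warns on sparse sites and needs two sites", {
  d <- tibble::tibble(x = c(1, 2, 3, 4, 5), y = c(2, 3, 4, 5, 7),
                      site = c("a", "a", "a", "a", "b"))
  expect_warning(
    suppressWarnings(
      fit_shared_slope(d, x, y, site, chains = 2, iter = 50,
                       burn = 50, thin = 1, seed = 1),
      classes = "simpleWarning"
    ),
    class = "pinnicomp_sparse_site"
  )
  d1 <- dplyr::mutate(d, site = "a")
  expect_error(fit_shared_slope(d1, x, y, site),
               class = "pinnicomp_domain_error")
})

test_that("heteroscedastic logit fit recovers its generating parameters", {
  d <- make_regression("logit", list(alpha0 = -1.6, alpha1 = -0.86,
                                     sigma = 0.2), n = 40, seed = 6)
  f <- fit_logit_water_fat(d, p_h2o, p_fat, chains = 2, iter = 800,
                           burn = 500, thin = 3, seed = 6)
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "alpha0"], -1.6, tolerance = 0.25)
  expect_equal(td$estimate[td$term == "alpha1"], -0.86, tolerance = 0.25)
  expect_error(
    fit_logit_water_fat(tibble::tibble(p_h2o = c(0, 0.5, 0.6),
                                       p_fat = c(0.2, 0.3, 0.4)),
                        p_h2o, p_fat),
    class = "pinnicomp_domain_error"
  )
})

test_that("a fitted logit regression becomes a usable conversion model", {
  d <- make_regression("logit", list(alpha0 = -1.6, alpha1 = -0.86,
                                     sigma = 0.2), n = 30, seed = 8)
  f <- fit_logit_water_fat(d, p_h2o, p_fat, chains = 2, iter = 400,
                           burn = 400, thin = 2, seed = 8)
  m <- as_water_fat_model(f)
  expect_s3_class(m, "pc_water_fat_model")
  expect_equal(m$alpha0, mean(f$draws$alpha0))
  draws <- fat_from_water_logit(0.6, m, posterior = TRUE, predictive = TRUE,
                                seed = 1)
  expect_equal(nrow(draws), nrow(f$draws))
  expect_true(all(draws$prop_fat > 0 & draws$prop_fat < 1))
})

test_that("diagnostics score injected chains as their mixing deserves", {
  set.seed(10)
  good <- tibble::tibble(.chain = rep(1:2, each = 500),
                         theta = rnorm(1000))
  dg <- mcmc_diagnostics(good)
  expect_lt(max(abs(dg$lag1$lag1)), 0.15)
  expect_true(dg$pass)

  stuck <- tibble::tibble(.chain = rep(1:2, each = 100),
                          theta = rep(c(0.3, 0.7), each = 100))
  ds <- mcmc_diagnostics(stuck)
  expect_equal(max(ds$lag1$lag1), 1)
  expect_false(ds$pass)

  expect_warning(mcmc_diagnostics(tibble::tibble(.chain = 1, theta = rnorm(50))),
                 class = "pinnicomp_single_chain")
})

test_that("glance summarises fit size and convergence in one row", {
  d <- make_regression("simple", list(beta0 = 0, beta1 = 1, sigma = 0.5),
                       n = 12, seed = 11)
  f <- fit_simple(d, x, y, chains = 2, iter = 400, burn = 400, thin = 4,
                  seed = 11)
  g <- glance(f)
  expect_equal(g$n_obs, 12)
  expect_equal(g$n_draws, 800)
  expect_gt(g$mean_acceptance, 0.15)
  expect_lt(g$mean_acceptance, 0.7)
})
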