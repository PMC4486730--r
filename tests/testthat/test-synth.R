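test_that("zero-noise synthetic seals are recovered exactly by the modified pipeline", {
  truth <- seal_truth()
  seal <- make_seal(truth, noise_model(0), seed = 1)
  est <- estimate_cones(seal, method = "modified", phase = "early")
  expect_equal(est$v_total_cm3, truth$truth$v_total_cm3, tolerance = 1e-12)
  expect_equal(est$v_skin_cm3, truth$truth$v_skin_cm3, tolerance = 1e-12)
  expect_equal(est$v_blubber_cm3, truth$truth$v_blubber_cm3,
               tolerance = 1e-12)
  expect_equal(est$blubber_mass_kg, truth$truth$blubber_mass_kg,
               tolerance = 1e-12)
  expect_equal(est$fat_mass_kg, truth$truth$fat_mass_kg, tolerance = 1e-12)
  expect_equal(est$prop_fat, truth$truth$prop_fat, tolerance = 1e-12)
})

test_that("a zero skin depth in the truth yields a zero skin shell estimate", {
  props0 <- tissue_properties(skin_depth_cm = 0)
  truth <- seal_truth(props = props0)
  seal <- make_seal(truth, noise_model(0), seed = 2)
  est <- estimate_cones(seal, method = "modified", props = props0,
                        phase = "early")
  expect_equal(est$v_skin_cm3, 0, tolerance = 1e-12)
  expect_equal(truth$truth$v_skin_cm3, 0, tolerance = 1e-12)
})

test_that("truth construction rejects tissue-nesting violations", {
  expect_error(
    seal_truth(sculp_dorsal_cm = c(pelvis = 40, umbilicus = 9, mid = 9,
                                   sternum = 8.5, axilla = 8, neck = 7)),
    class = "pinnicomp_nesting_error"
  )
  expect_error(
    seal_truth(sculp_dorsal_cm = c(pelvis = 0.5, umbilicus = 9, mid = 9,
                                   sternum = 8.5, axilla = 8, neck = 7)),
    class = "pinnicomp_nesting_error"
  )
})

test_that("noisy estimates are centred on the truth", {
  truth <- seal_truth()
  ests <- vapply(1:120, function(s) {
    seal <- make_seal(truth, noise_model(1), seed = s)
    estimate_cones(seal, method = "modified", phase = "early")$prop_fat
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  # bias small relative to the spread of a single estimate
  expect_lt(abs(mean(ests) - truth$truth$prop_fat),
            max(3 * se, 0.1 * sd(ests)))
})

test_that("generators are pure functions of their seed", {
  truth <- seal_truth()
  expect_identical(make_seal(truth, noise_model(1), seed = 42),
                   make_seal(truth, noise_model(1), seed = 42))
  expect_false(identical(make_seal(truth, noise_model(1), seed = 42),
                         make_seal(truth, noise_model(1), seed = 43)))
  expect_identical(make_dilution(2e5, noise = noise_model(1), seed = 9),
                   make_dilution(2e5, noise = noise_model(1), seed = 9))
  expect_identical(make_regression("logit", n = 15, seed = 3),
                   make_regression("logit", n = 15, seed = 3))
})

test_that("zero-noise dilution experiments invert exactly; no signal raises", {
  dl <- make_dilution(200000, mass_kg = 400, noise = noise_model(0))
  got <- estimate_tbw(dl$injections, dl$blood, dl$standards)
  expect_equal(got$tbw_ml, 200000, tolerance = 1e-12)
  # nothing injected: equilibrium equals background by construction
  dl0 <- make_dilution(200000, mass_kg = 400, injected_g = 0,
                       noise = noise_model(0))
  expect_error(estimate_tbw(dl0$injections, dl0$blood, dl0$standards),
               class = "pinnicomp_no_signal")
})

test_that("noisy dilution recovery improves with replicate counts", {
  noisy <- noise_model(1, count_cv = 0.05)
  dl <- make_dilution(200000, mass_kg = 400, n_replicates = 100,
                      n_standards = 3, noise = noisy, seed = 4)
  got <- estimate_tbw(dl$injections, dl$blood, dl$standards)
  expect_lt(abs(got$tbw_ml - 200000) / 200000, 0.01)
})

test_that("regression generators honour their likelihoods", {
  exact <- make_regression("simple", list(beta0 = 2, beta1 = -1, sigma = 0),
                           n = 10, seed = 1)
  expect_equal(exact$y, 2 - exact$x, tolerance = 1e-12)

  d <- make_regression("logit", list(alpha0 = -1.6, alpha1 = -0.86,
                                     sigma = 0.3, p_h2o_range = c(0.3, 0.8)),
                       n = 4000, seed = 2)
  xr <- d$p_h2o / (1 - d$p_h2o)
  resid <- (qlogis(d$p_fat) - (-1.6 - 0.86 * xr))
  lo <- sd(resid[xr < quantile(xr, 0.3)])
  hi <- sd(resid[xr > quantile(xr, 0.7)])
  # residual spread grows with the water ratio
  expect_gt(hi / lo, 1.5)
})
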