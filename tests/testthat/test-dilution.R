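test_that("stock specific activity back-scales by the dilution factor", {
  one <- stock_specific_activity(tibble::tibble(
    aliquot_ml = 0.01, diluent_ml = 1000, cpm_ml = 50))
  expect_equal(one$mean_cpm_ml, 50 * 1000.01 / 0.01)
  expect_equal(one$sd_cpm_ml, 0)

  two <- stock_specific_activity(tibble::tibble(
    aliquot_ml = 0.01, diluent_ml = 1000, cpm_ml = c(42, 42)))
  expect_equal(two$sd_cpm_ml, 0)

  reps <- stock_specific_activity(tibble::tibble(
    aliquot_ml = 0.01, diluent_ml = 1000, cpm_ml = c(40, 60)))
  expect_equal(reps$mean_cpm_ml, mean(c(40, 60) * 1000.01 / 0.01))
  expect_error(
    stock_specific_activity(tibble::tibble(
      aliquot_ml = 0.01, diluent_ml = 1000, cpm_ml = 5,
      background_cpm_ml = 10)),
    class = "pinnicomp_counting_error"
  )
})

test_that("total body water is injected activity over net concentration", {
  expect_equal(tbw(1e6, 100, 0), 10000)
  expect_equal(tbw(5e5, 60, 10), 10000)
  expect_error(tbw(1e6, 50, 50), class = "pinnicomp_no_signal")
  # homogeneity: scaling activity and net concentration together cancels
  expect_equal(tbw(3 * 1e6, 3 * 80, 3 * 20), tbw(1e6, 80, 20))
})

test_that("proportion water bounds against body mass", {
  expect_equal(proportion_water(240000, 400), 0.6)
  expect_equal(proportion_water(0, 400), 0)
  expect_error(proportion_water(4e5, 400), class = "pinnicomp_inconsistency")
})

test_that("logit conversion matches hand arithmetic and stays inside (0,1)", {
  m_pos <- water_fat_model("logit", alpha0 = -1.6, alpha1 = 0.86)
  expect_equal(fat_from_water_logit(0.5, m_pos), plogis(-1.6 + 0.86),
               tolerance = 1e-12)
  expect_equal(fat_from_water_logit(0.5, m_pos), 0.32300, tolerance = 1e-4)
  m <- water_fat_model("logit")  # alpha1 = -0.86
  expect_equal(fat_from_water_logit(1e-9, m), plogis(m$alpha0),
               tolerance = 1e-6)
  grid <- seq(0.01, 0.99, by = 0.01)
  out <- fat_from_water_logit(grid, m)
  expect_true(all(out > 0 & out < 1))
  # monotone, direction set by the slope sign
  expect_true(all(diff(out) < 0))
  interior <- seq(0.05, 0.9, by = 0.01)
  expect_true(all(diff(fat_from_water_logit(interior, m_pos)) > 0))
  expect_error(fat_from_water_logit(0, m), class = "pinnicomp_domain_error")
  expect_error(fat_from_water_logit(1, m), class = "pinnicomp_domain_error")
})

test_that("linear rule goes negative above 1/1.37 and flags it", {
  expect_equal(fat_from_water_iverson(0.5), 0.315)
  expect_equal(fat_from_water_iverson(1 / 1.37), 0, tolerance = 1e-12)
  expect_warning(neg <- fat_from_water_iverson(0.8),
                 class = "pinnicomp_negative_fat")
  expect_equal(neg, -0.096)
})

test_that("tissue-water rule interpolates between the all-lean and all-adipose limits", {
  m <- water_fat_model("pace_rathbun", w_a = 0.2, w_l = 0.7, f_a = 0.9,
                       adjustment = 1)
  expect_equal(adipose_and_fat_from_water_pr(0.7 - 1e-12, m)$prop_adipose, 0,
               tolerance = 1e-9)
  expect_equal(adipose_and_fat_from_water_pr(0.2, m)$prop_adipose, 1)
  mid <- adipose_and_fat_from_water_pr(0.45, m)
  expect_equal(mid$prop_adipose, 0.5)
  expect_equal(mid$prop_fat, 0.45)
  # linear and decreasing between the limits
  pw <- seq(0.25, 0.65, by = 0.05)
  ad <- adipose_and_fat_from_water_pr(pw, m)$prop_adipose
  expect_rel_equal(diff(ad), diff(ad)[1], tol = 1e-9)
  expect_lt(diff(ad)[1], 0)
  expect_warning(adipose_and_fat_from_water_pr(0.75, m),
                 class = "pinnicomp_out_of_model")
  draws <- adipose_and_fat_from_water_pr(
    0.45, water_fat_model("pace_rathbun"), n_draws = 500, seed = 2)
  expect_equal(nrow(draws), 500)
  expect_true(all(draws$prop_adipose >= 0 & draws$prop_adipose <= 1))
})

test_that("the water bias adjustment rescales proportion water before conversion", {
  m1 <- water_fat_model("pace_rathbun", w_a = 0.2, w_l = 0.7, f_a = 0.9,
                        adjustment = 1)
  m2 <- water_fat_model("pace_rathbun", w_a = 0.2, w_l = 0.7, f_a = 0.9,
                        adjustment = 0.967)
  p <- 0.5
  expect_equal(adipose_and_fat_from_water_pr(p, m2)$prop_adipose,
               adipose_and_fat_from_water_pr(0.967 * p, m1)$prop_adipose)
})

test_that("estimate_tbw composes stock, blood and injection tables", {
  dl <- make_dilution(c(200000, 250000), mass_kg = c(400, 420),
                      noise = noise_model(0))
  got <- estimate_tbw(dl$injections, dl$blood, dl$standards)
  expect_equal(got$tbw_ml, c(200000, 250000), tolerance = 1e-12)
  expect_equal(got$prop_water, c(0.5, 250 / 420), tolerance = 1e-12)
})
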