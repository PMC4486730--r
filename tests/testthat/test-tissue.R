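test_that("skin density from a core section follows the two-layer mass balance", {
  # core all skin, or homogeneous core: both collapse to the core density
  expect_equal(skin_density_from_core(0.93, 0.89, 1.32, 1.32), 0.93)
  expect_equal(skin_density_from_core(0.93, 0.93, 4, 1.32), 0.93)
  expect_equal(skin_density_from_core(0.93, 0.89, 4.00, 1.32), 1.0112,
               tolerance = 1e-4)
  expect_error(skin_density_from_core(0.93, 0.89, 4, 0),
               class = "pinnicomp_domain_error")
  expect_error(skin_density_from_core(0.93, 0.89, 1, 1.32),
               class = "pinnicomp_domain_error")
})

test_that("traditional estimate applies the literature sculp constants", {
  d <- tibble::tibble(v_blubber_cm3 = 1e5, mass_kg = 400)
  est <- traditional_estimate(d)
  expect_equal(est$blubber_mass_kg, 94)
  expect_equal(est$fat_mass_kg, 84.882)
  expect_equal(est$prop_fat, 84.882 / 400)
  zero <- traditional_estimate(tibble::tibble(v_blubber_cm3 = 0, mass_kg = 400))
  expect_equal(zero$fat_mass_kg, 0)
  expect_error(
    traditional_estimate(tibble::tibble(v_blubber_cm3 = 1, mass_kg = 0)),
    class = "pinnicomp_domain_error"
  )
})

test_that("modified estimate separates blubber and skin with phase-specific fat", {
  d <- tibble::tibble(v_total_cm3 = 4e5, v_skin_cm3 = 1e4,
                      v_blubber_cm3 = 1e5, v_core_cm3 = 2.9e5, mass_kg = 400)
  early <- modified_estimate(d, phase = "early")
  expect_equal(early$blubber_mass_kg, 89)
  expect_equal(early$blubber_fat_kg, 75.917)
  late <- modified_estimate(d, phase = "late")
  expect_equal(late$blubber_fat_kg, 73.247)
  expect_equal(early$skin_mass_kg, 11.7)
  expect_equal(early$skin_fat_kg, 1.8837)
  expect_equal(early$fat_mass_kg, 75.917 + 1.8837)
  expect_equal(early$prop_adipose, 89 / 400)
})

test_that("modified estimate is linear: doubling volumes doubles masses", {
  d <- tibble::tibble(v_total_cm3 = 4e5, v_skin_cm3 = 1e4,
                      v_blubber_cm3 = 1e5, v_core_cm3 = 2.9e5, mass_kg = 400)
  one <- modified_estimate(d, phase = "late")
  two <- modified_estimate(dplyr::mutate(d, dplyr::across(
    dplyr::starts_with("v_"), ~ 2 * .x)), phase = "late")
  expect_equal(two$fat_mass_kg, 2 * one$fat_mass_kg)
  expect_equal(two$blubber_mass_kg, 2 * one$blubber_mass_kg)
  # fat never exceeds the tissue masses it came from
  expect_lte(one$fat_mass_kg, one$blubber_mass_kg + one$skin_mass_kg)
})

test_that("body densities follow mass over volume", {
  expect_equal(total_body_density(100, 1e5), 1)
  expect_equal(total_body_density(94, 1e5), 0.94)
  expect_error(total_body_density(94, 0), class = "pinnicomp_domain_error")

  # construct a body whose non-blubber density is 1.2 by choosing the mass
  part <- tibble::tibble(v_total_cm3 = 1e5, v_skin_cm3 = 5e3,
                         v_blubber_cm3 = 3e4, v_core_cm3 = 6.5e4)
  blubber_mass <- part$v_blubber_cm3 * 0.89 / 1000
  part$mass_kg <- (part$v_total_cm3 - part$v_blubber_cm3) * 1.2 / 1000 +
    blubber_mass
  got <- non_blubber_density(part)
  expect_equal(got$non_blubber_density, 1.2)

  # all-core body: non-blubber density equals total body density
  allcore <- tibble::tibble(v_total_cm3 = 1e5, v_blubber_cm3 = 0,
                            mass_kg = 110)
  expect_equal(non_blubber_density(allcore)$non_blubber_density,
               total_body_density(110, 1e5))
  expect_error(
    non_blubber_density(tibble::tibble(v_total_cm3 = 1e5,
                                       v_blubber_cm3 = 1e5, mass_kg = 89)),
    class = "pinnicomp_inconsistency"
  )
})

test_that("sculp summaries interpolate between the pure-tissue properties", {
  eq <- tibble::tibble(v_skin_cm3 = 1000, v_blubber_cm3 = 1000)
  got <- sculp_summary(eq, phase = "early")
  expect_equal(got$sculp_density, (1.17 + 0.89) / 2)
  allb <- sculp_summary(tibble::tibble(v_skin_cm3 = 0, v_blubber_cm3 = 1000),
                        phase = "early")
  expect_equal(allb$sculp_fat_fraction, 0.853)
  alls <- sculp_summary(tibble::tibble(v_skin_cm3 = 1000, v_blubber_cm3 = 0),
                        phase = "early")
  expect_equal(alls$sculp_fat_fraction, 0.161)
  # a realistic mix lands strictly between the pure-tissue bounds
  mix <- sculp_summary(tibble::tibble(v_skin_cm3 = 12, v_blubber_cm3 = 30),
                       phase = "late")
  expect_gt(mix$sculp_fat_fraction, 0.161)
  expect_lt(mix$sculp_fat_fraction, 0.823)
  expect_error(
    sculp_summary(tibble::tibble(v_skin_cm3 = 0, v_blubber_cm3 = 0)),
    class = "pinnicomp_domain_error"
  )
})

test_that("tissue properties validate and override cleanly", {
  p <- tissue_properties()
  expect_equal(p$blubber_density[["mean"]], 0.89)
  expect_equal(p$fat_in_blubber_late[["sd"]], 0.031)
  p2 <- tissue_properties(blubber_density = c(mean = 0.92, sd = 0.01))
  expect_equal(p2$blubber_density[["mean"]], 0.92)
  expect_error(tissue_properties(fat_in_skin = 1.5),
               class = "pinnicomp_config_error")
  expect_error(tissue_properties(skin_density = -1),
               class = "pinnicomp_config_error")
})
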