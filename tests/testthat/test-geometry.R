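test_that("straight length recovers right-triangle legs and rejects degenerate segments", {
  expect_equal(straight_length(5, 4, 1), 4)
  expect_equal(straight_length(10, 3, 3), 10)
  expect_equal(straight_length(13, 6, 1), 12)
  expect_lte(straight_length(7.3, 2.1, 0.4), 7.3)
  expect_error(straight_length(3, 5, 1), class = "pinnicomp_degenerate_segment")
  expect_error(straight_length(4, 5, 1), class = "pinnicomp_degenerate_segment")
})

test_that("frustum volume matches closed forms and rejects negative inputs", {
  expect_equal(frustum_volume(1, 1, 1, 1, 3), 3 * pi)
  expect_equal(frustum_volume(1, 2, 0, 0, 3), 2 * pi)
  expect_equal(frustum_volume(2, 1, 1, 0.5, 6), 7 * pi)
  expect_equal(end_cone_volume(1, 1, 3), pi)
  expect_equal(end_cone_volume(2, 1, 3), 2 * pi)
  expect_equal(end_cone_volume(0, 1, 5), 0)
  expect_error(frustum_volume(-1, 1, 1, 1, 3), class = "pinnicomp_domain_error")
  expect_error(end_cone_volume(1, 1, -2), class = "pinnicomp_domain_error")
})

test_that("frustum volume equals the quadrature oracle on random frusta", {
  fr <- random_frusta(200, seed = 11)
  got <- frustum_volume(fr$a1, fr$b1, fr$a2, fr$b2, fr$l_s)
  want <- mapply(oracle_frustum, fr$a1, fr$b1, fr$a2, fr$b2, fr$l_s)
  expect_rel_equal(got, want, tol = 1e-12)
})

test_that("frustum limits: cylinder and end cone", {
  fr <- random_frusta(50, seed = 12)
  expect_equal(frustum_volume(fr$a1, fr$b1, fr$a1, fr$b1, fr$l_s),
               pi * fr$a1 * fr$b1 * fr$l_s)
  expect_equal(frustum_volume(fr$a1, fr$b1, 0, 0, fr$l_s),
               end_cone_volume(fr$a1, fr$b1, fr$l_s))
})

test_that("volume grows strictly with every semi-axis and the length", {
  base <- frustum_volume(2, 3, 1.5, 2.5, 10)
  eps <- 1e-3
  expect_gt(frustum_volume(2 + eps, 3, 1.5, 2.5, 10), base)
  expect_gt(frustum_volume(2, 3 + eps, 1.5, 2.5, 10), base)
  expect_gt(frustum_volume(2, 3, 1.5 + eps, 2.5, 10), base)
  expect_gt(frustum_volume(2, 3, 1.5, 2.5 + eps, 10), base)
  expect_gt(frustum_volume(2, 3, 1.5, 2.5, 10 + eps), base)
})

test_that("a cylindrical trunk gives the textbook volume in both shape modes", {
  prof <- cylinder_trunk(r = 10, length = 100)
  ell <- body_volume(prof, shape = "elliptical", extent = "neck_to_pelvis")
  circ <- body_volume(prof, shape = "circular", extent = "neck_to_pelvis")
  expect_equal(ell$volume_cm3, 10000 * pi)
  expect_equal(circ$volume_cm3, ell$volume_cm3)
})

test_that("circular and elliptical modes agree whenever height equals width", {
  prof <- random_seal_profile(21) |>
    dplyr::mutate(height_cm = (height_cm + width_cm) / 2,
                  width_cm = height_cm,
                  girth_cm = pi * height_cm)
  ell <- body_volume(prof, "elliptical", "full_body")
  circ <- body_volume(prof, "circular", "full_body")
  expect_equal(circ$volume_cm3, ell$volume_cm3, tolerance = 1e-12)
})

test_that("body volume of a piecewise-linear body matches per-segment quadrature", {
  prof <- summarise_replicates(random_seal_profile(31))
  bv <- body_volume(prof, "elliptical", "full_body")
  seg <- bv$segments[[1]]
  st <- prof[order(match(prof$site, cone_sites()$site)), ]
  a <- st$width_cm / 2
  b <- st$height_cm / 2
  want <- mapply(oracle_frustum, a[-8], b[-8], a[-1], b[-1], seg$straight_cm)
  expect_rel_equal(seg$volume_cm3, want, tol = 1e-10)
  expect_equal(sum(seg$volume_cm3) + bv$cone_posterior_cm3 +
                 bv$cone_anterior_cm3, bv$volume_cm3)
})

test_that("missing sites and absent heights raise schema errors", {
  prof <- cylinder_trunk()
  expect_error(body_volume(prof, extent = "full_body"),
               class = "pinnicomp_schema_error")
  prof_noh <- dplyr::select(prof, -height_cm)
  expect_error(body_volume(prof_noh, "elliptical", "neck_to_pelvis"),
               class = "pinnicomp_schema_error")
  expect_equal(
    body_volume(prof_noh, "circular", "neck_to_pelvis")$volume_cm3,
    10000 * pi
  )
})

test_that("shell partition of a cylinder reduces to annulus arithmetic", {
  prof <- cylinder_trunk(r = 10, length = 100, us = 3)
  part <- partition_volumes(prof, skin_depth = 1, shape = "circular",
                            extent = "neck_to_pelvis")
  expect_equal(part$v_total_cm3, 10000 * pi)
  expect_equal(part$v_skin_cm3, 1900 * pi)
  expect_equal(part$v_blubber_cm3, 3200 * pi)
  expect_equal(part$v_core_cm3, 4900 * pi)
})

test_that("zero skin depth and zero sculp depth leave everything as core", {
  prof <- cylinder_trunk(r = 10, length = 100, us = 0)
  part <- partition_volumes(prof, skin_depth = 0, shape = "circular",
                            extent = "neck_to_pelvis")
  expect_equal(part$v_skin_cm3, 0)
  expect_equal(part$v_blubber_cm3, 0)
  expect_equal(part$v_core_cm3, part$v_total_cm3)
})

test_that("partition components are non-negative and sum to the total", {
  for (seed in c(41, 42, 43, 44, 45)) {
    prof <- random_seal_profile(seed)
    part <- partition_volumes(prof, skin_depth = 1.32, shape = "elliptical",
                              extent = "full_body")
    expect_equal(part$v_skin_cm3 + part$v_blubber_cm3 + part$v_core_cm3,
                 part$v_total_cm3, tolerance = 1e-12)
    expect_true(all(c(part$v_skin_cm3, part$v_blubber_cm3,
                      part$v_core_cm3) >= 0))
  }
})

test_that("over-deep sculp readings clamp with a warning; thick skin errors", {
  prof <- cylinder_trunk(r = 5, length = 100, us = 6)
  expect_warning(
    part <- partition_volumes(prof, skin_depth = 1, shape = "circular",
                              extent = "neck_to_pelvis"),
    class = "pinnicomp_clamped"
  )
  expect_equal(part$v_core_cm3, 0)
  expect_gte(part$v_blubber_cm3, 0)
  expect_error(
    partition_volumes(prof, skin_depth = 5, shape = "circular",
                      extent = "neck_to_pelvis"),
    class = "pinnicomp_degenerate_body"
  )
})

test_that("ultrasound depth conversion applies the shared slope and site intercept", {
  cal <- default_ultrasound_calibration("dorsal")
  expect_equal(convert_ultrasound_depth(2, "pelvis", cal), 3.006)
  expect_equal(convert_ultrasound_depth(0, "neck", cal), 0.540)
  ident <- ultrasound_calibration(1, c(pelvis = 0, mid = 0), surface = "dorsal")
  expect_equal(convert_ultrasound_depth(c(1.2, 4.5), c("pelvis", "mid"), ident),
               c(1.2, 4.5))
  expect_error(convert_ultrasound_depth(1, "flipper", cal),
               class = "pinnicomp_unknown_site")
  expect_error(convert_ultrasound_depth(1, "pelvis", cal, posterior = TRUE),
               class = "pinnicomp_no_draws")
})
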