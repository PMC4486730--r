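# Independent oracles and small profile builders used across tests.

# Quadrature oracle for the elliptical frustum: the cross-sectional area
# pi * a(t) * b(t) with a, b linear in t is quadratic, so a single Simpson
# rule integrates it exactly -- independently of the closed form under test.
oracle_frustum <- function(a1, b1, a2, b2, l_s) {
  f <- function(t) {
    a <- a1 + (a2 - a1) * t
    b <- b1 + (b2 - b1) * t
    pi * a * b
  }
  l_s * (f(0) + 4 * f(0.5) + f(1)) / 6
}

# A trunk-only "cylinder seal": all six interior sites with identical
# semi-axes, equally spaced curvilinear stations, constant sculp depths.
cylinder_trunk <- function(r = 10, length = 100, us = 3, height = 2 * r,
                           width = 2 * r, mass_kg = 100) {
  sites <- c("pelvis", "umbilicus", "mid", "sternum", "axilla", "neck")
  tibble::tibble(
    animal_id = "cyl",
    site = sites,
    girth_cm = 2 * pi * r,
    height_cm = height,
    width_cm = width,
    curvilinear_cm = seq(0, length, length.out = 6) + 10,
    us_dorsal_cm = us,
    us_lateral_cm = us,
    total_length_cm = length + 40,
    mass_kg = mass_kg
  )
}

# Random valid frustum parameters for property checks.
random_frusta <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    a1 = runif(n, 0.1, 50), b1 = runif(n, 0.1, 50),
    a2 = runif(n, 0, 50), b2 = runif(n, 0, 50),
    l_s = runif(n, 0.1, 80)
  )
}

# Perturbed copies of the default synthetic seal for partition properties.
random_seal_profile <- function(seed) {
  truth <- seal_truth()
  make_seal(truth, noise_model(1), animal_id = paste0("rnd_", seed),
            seed = seed)
}

expect_rel_equal <- function(actual, expected, tol = 1e-12) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
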