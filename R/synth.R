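# Synthetic seals, dilution experiments and regression datasets with known
# ground truth. Truth bodies are piecewise elliptical frusta -- inside the
# estimator's model class -- so the whole cones pipeline recovers them
# exactly at zero measurement noise.

#' Define a synthetic seal with known tissue composition
#'
#' The body is a stack of elliptical frusta over the eight landmark sites
#' with end cones at nose and tail. Three nested surfaces are defined: the
#' outer body, the skin boundary (outer eroded by the uniform skin depth)
#' and the blubber--muscle boundary (outer eroded by the site-specific sculp
#' depths; coincides with the skin boundary at the ears and ankles, and over
#' the end cones). True tissue volumes use the same frustum arithmetic the
#' estimator uses; masses follow from tissue densities and total body water
#' from tissue water fractions. Defaults describe a molting adult female
#' elephant seal of roughly 400 kg with about 30% of its mass in the sculp.
#'
#' @param semi_axes Tibble with columns `site`, `a_cm` (horizontal semi-axis)
#'   and `b_cm` (vertical semi-axis) for all eight sites.
#' @param segment_cm Axial lengths of the seven inter-site segments
#'   (ankles to ears).
#' @param cone_cm Axial lengths `c(posterior, anterior)` of the tail and
#'   nose end cones.
#' @param sculp_dorsal_cm,sculp_lateral_cm Named sculp depths (cm) at the
#'   six interior sites.
#' @param props [tissue_properties()] used for skin depth and densities.
#' @param core_density Density of non-sculp tissue (g/mL).
#' @param w_adipose,w_lean Water fractions of adipose and lean tissue, for
#'   the true total body water.
#' @param phase Molt phase (sets the blubber fat fraction).
#' @return An object of class `pc_seal_truth` with the geometry, the derived
#'   true volumes/masses (`$truth`, a one-row tibble), and the inputs.
#' @export
#' @examples
#' st <- seal_truth()
#' st$truth$mass_kg
seal_truth <- function(semi_axes = NULL,
                       segment_cm = c(35, 33, 30, 30, 30, 28, 30),
                       cone_cm = c(posterior = 15, anterior = 35),
                       sculp_dorsal_cm = c(pelvis = 8.5, umbilicus = 9.0,
                                           mid = 9.0, sternum = 8.5,
                                           axilla = 8.0, neck = 7.0),
                       sculp_lateral_cm = c(pelvis = 7.5, umbilicus = 8.0,
                                            mid = 8.0, sternum = 7.5,
                                            axilla = 7.0, neck = 6.0),
                       props = tissue_properties(),
                       core_density = 1.15,
                       w_adipose = 0.144, w_lean = 0.732,
                       phase = c("early", "late")) {
  phase <- match.arg(phase)
  if (is.null(semi_axes)) {
    semi_axes <- tibble::tibble(
      site = cone_sites()$site,
      a_cm = c(11, 23, 30, 32, 31, 28, 21, 11),
      b_cm = c(9, 20, 25, 27, 26, 23, 18, 10)
    )
  }
  st <- dplyr::left_join(cone_sites(), semi_axes, by = "site")
  if (anyNA(st$a_cm) || anyNA(st$b_cm)) {
    rlang::abort("semi_axes must cover all eight sites.",
                 class = "pinnicomp_schema_error")
  }
  skin <- prop_mean(props, "skin_depth_cm")
  interior <- st$interior
  d_a <- d_b <- rep(skin, 8)
  d_a[interior] <- unname(sculp_lateral_cm[st$site[interior]])
  d_b[interior] <- unname(sculp_dorsal_cm[st$site[interior]])
  if (anyNA(d_a) || anyNA(d_b)) {
    rlang::abort("Sculp depths required for all six interior sites.",
                 class = "pinnicomp_schema_error")
  }
  a_skin <- st$a_cm - skin
  b_skin <- st$b_cm - skin
  a_in <- st$a_cm - d_a
  b_in <- st$b_cm - d_b
  if (any(a_in <= 0) || any(b_in <= 0) || any(d_a < skin) || any(d_b < skin)) {
    rlang::abort(
      "Tissue nesting violated: need 0 < inner boundary <= skin boundary.",
      class = "pinnicomp_nesting_error")
  }
  ax <- list(segments = segment_cm,
             cones = list(posterior = unname(cone_cm[1]),
                          anterior = unname(cone_cm[2])))
  v_total <- stack_volume(st$a_cm, st$b_cm, ax)$total
  v_minus_skin <- stack_volume(a_skin, b_skin, ax)$total
  v_inner <- stack_volume(a_in, b_in, ax)$total
  v_skin <- v_total - v_minus_skin
  v_blubber <- v_minus_skin - v_inner
  rho_b <- prop_mean(props, "blubber_density")
  rho_d <- prop_mean(props, "skin_density")
  f_b <- prop_mean(props, paste0("fat_in_blubber_", phase))
  f_d <- prop_mean(props, "fat_in_skin")
  m_blubber <- v_blubber * rho_b / 1000
  m_skin <- v_skin * rho_d / 1000
  m_core <- v_inner * core_density / 1000
  mass <- m_blubber + m_skin + m_core
  fat <- m_blubber * f_b + m_skin * f_d
  tbw_ml <- 1000 * (w_adipose * m_blubber + w_lean * (mass - m_blubber))
  truth <- tibble::tibble(
    v_total_cm3 = v_total, v_skin_cm3 = v_skin,
    v_blubber_cm3 = v_blubber, v_core_cm3 = v_inner,
    blubber_mass_kg = m_blubber, skin_mass_kg = m_skin,
    core_mass_kg = m_core, mass_kg = mass,
    fat_mass_kg = fat, prop_fat = fat / mass,
    prop_adipose = m_blubber / mass,
    tbw_ml = tbw_ml, prop_water = tbw_ml / (1000 * mass)
  )
  structure(
    list(sites = st, segment_cm = segment_cm, cone_cm = cone_cm,
         sculp_dorsal_cm = sculp_dorsal_cm,
         sculp_lateral_cm = sculp_lateral_cm,
         skin_depth_cm = skin, props = props, core_density = core_density,
         w_adipose = w_adipose, w_lean = w_lean, phase = phase,
         truth = truth),
    class = "pc_seal_truth"
  )
}

#' @export
print.pc_seal_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic seal: %.0f kg, %.0f L, prop fat %.3f, prop water %.3f (%s molt)>\n",
    x$truth$mass_kg, x$truth$v_total_cm3 / 1000, x$truth$prop_fat,
    x$truth$prop_water, x$phase))
  invisible(x)
}

#' Measurement noise model for synthetic seals
#'
#' Additive normal noise on tape measurements, multiplicative lognormal
#' noise on ultrasound depth readings, and a coefficient of variation for
#' scintillation counts. `noise_model(0)` is the exact, noise-free observer.
#'
#' @param scale Multiplies every default SD (0 = no noise).
#' @param girth_sd,height_sd,width_sd,length_sd,total_length_sd Additive
#'   SDs in cm.
#' @param us_sdlog Log-scale SD of ultrasound readings.
#' @param count_cv Coefficient of variation of scintillation counts.
#' @param observers Number of independent replicate measurements.
#' @return An object of class `pc_noise_model`.
#' @export
noise_model <- function(scale = 1, girth_sd = 0.8 * scale,
                        height_sd = 0.5 * scale, width_sd = 0.5 * scale,
                        length_sd = 1.0 * scale,
                        total_length_sd = 1.5 * scale,
                        us_sdlog = 0.06 * scale,
                        count_cv = 0.02 * scale,
                        observers = 3) {
  vals <- c(girth_sd, height_sd, width_sd, length_sd, total_length_sd,
            us_sdlog, count_cv)
  if (any(vals < 0)) {
    rlang::abort("Noise SDs must be non-negative.",
                 class = "pinnicomp_config_error")
  }
  structure(
    list(girth_sd = girth_sd, height_sd = height_sd, width_sd = width_sd,
         length_sd = length_sd, total_length_sd = total_length_sd,
         us_sdlog = us_sdlog, count_cv = count_cv, observers = observers),
    class = "pc_noise_model"
  )
}

# Ellipse perimeter (Ramanujan's first approximation); the generator needs a
# girth for the circular pipeline even though the estimator never inverts it.
ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Generate noisy morphometric measurements of a synthetic seal
#'
#' Emits the replicate measurement table an observer team would produce:
#' per-site girths, heights, widths, curvilinear lengths and sculp depths,
#' plus total length and mass. Curvilinear lengths are constructed from the
#' truth's axial geometry so that, at zero noise, the straight-length and
#' volume reconstruction is exact.
#'
#' @param truth A [seal_truth()].
#' @param noise A [noise_model()].
#' @param animal_id Identifier written to the table.
#' @param seed Random seed.
#' @return A morphometric tibble (one row per replicate x site) matching the
#'   [read_morphometrics()] schema.
#' @export
#' @examples
#' make_seal(seal_truth(), noise_model(0), seed = 1)
make_seal <- function(truth, noise = noise_model(), animal_id = "synth_01",
                      seed = 1) {
  stopifnot(inherits(truth, "pc_seal_truth"),
            inherits(noise, "pc_noise_model"))
  set.seed(seed)
  st <- truth$sites
  b <- st$b_cm
  # curvilinear stations consistent with the axial geometry
  lc <- numeric(8)
  lc[1] <- sqrt(truth$cone_cm[[1]]^2 + b[1]^2)
  for (i in 1:7) {
    lc[i + 1] <- lc[i] + sqrt(truth$segment_cm[i]^2 + (b[i + 1] - b[i])^2)
  }
  total_len <- lc[8] + sqrt(truth$cone_cm[[2]]^2 + b[8]^2)
  girth <- ellipse_perimeter(st$a_cm, st$b_cm)
  d_dors <- d_lat <- rep(NA_real_, 8)
  d_dors[st$interior] <- unname(truth$sculp_dorsal_cm[st$site[st$interior]])
  d_lat[st$interior] <- unname(truth$sculp_lateral_cm[st$site[st$interior]])

  purrr::map_dfr(seq_len(noise$observers), function(rep_i) {
    mult_us <- function(x) {
      ifelse(is.na(x), NA_real_,
             x * stats::rlnorm(length(x), 0, noise$us_sdlog))
    }
    tibble::tibble(
      animal_id = animal_id,
      replicate = rep_i,
      site = st$site,
      girth_cm = girth + stats::rnorm(8, 0, noise$girth_sd),
      height_cm = 2 * st$b_cm + stats::rnorm(8, 0, noise$height_sd),
      width_cm = 2 * st$a_cm + stats::rnorm(8, 0, noise$width_sd),
      curvilinear_cm = lc + stats::rnorm(8, 0, noise$length_sd),
      us_dorsal_cm = mult_us(d_dors),
      us_lateral_cm = mult_us(d_lat),
      total_length_cm = total_len + stats::rnorm(1, 0, noise$total_length_sd),
      mass_kg = truth$truth$mass_kg
    )
  })
}

#' Generate a synthetic labeled-water dilution experiment
#'
#' Builds the three count tables (injection, blood, standards) for animals
#' with known total body water, by inverting the dilution arithmetic:
#' equilibrium concentration is injected activity over TBW plus background.
#' At zero count noise [estimate_tbw()] recovers the truth exactly.
#'
#' @param true_tbw_ml True total body water, one value per animal (mL).
#' @param mass_kg Body masses (recycled).
#' @param stock_cpm_ml Specific activity of the injectate stock (CPM/mL).
#' @param injected_g Injected mass of labeled saline (g; 1 g/mL).
#' @param bg_cpm_ml Background activity concentration (CPM/mL).
#' @param aliquot_ml,diluent_ml Standard dilution geometry.
#' @param n_standards,n_replicates Standards and count replicates.
#' @param noise A [noise_model()] (only `count_cv` is used).
#' @param seed Random seed.
#' @return A list of tibbles `injections`, `blood`, `standards`, plus
#'   `true_tbw_ml`.
#' @export
#' @examples
#' dl <- make_dilution(200000, mass_kg = 400, noise = noise_model(0))
#' estimate_tbw(dl$injections, dl$blood, dl$standards)$tbw_ml
make_dilution <- function(true_tbw_ml, mass_kg = NA_real_,
                          stock_cpm_ml = 2e7, injected_g = 5,
                          bg_cpm_ml = 30, aliquot_ml = 0.01,
                          diluent_ml = 1000, n_standards = 3,
                          n_replicates = 3, noise = noise_model(),
                          seed = 1) {
  stopifnot(all(true_tbw_ml > 0))
  set.seed(seed)
  n_animal <- length(true_tbw_ml)
  ids <- sprintf("synth_%02d", seq_len(n_animal))
  mass_kg <- rep_len(mass_kg, n_animal)
  injected_g <- rep_len(injected_g, n_animal)
  cv <- noise$count_cv
  noisy <- function(x) x * (1 + stats::rnorm(length(x), 0, cv))

  injections <- tibble::tibble(animal_id = ids, injected_g = injected_g,
                               mass_kg = mass_kg)
  eq_true <- injected_g * stock_cpm_ml / true_tbw_ml + bg_cpm_ml
  blood <- purrr::map_dfr(seq_len(n_animal), function(i) {
    tibble::tibble(
      animal_id = ids[i],
      replicate = rep(seq_len(n_replicates), 2),
      role = rep(c("equilibrium", "background"), each = n_replicates),
      cpm_ml = c(noisy(rep(eq_true[i], n_replicates)),
                 noisy(rep(bg_cpm_ml, n_replicates)))
    )
  })
  conc_true <- stock_cpm_ml * aliquot_ml / (aliquot_ml + diluent_ml)
  standards <- purrr::map_dfr(seq_len(n_standards), function(s) {
    tibble::tibble(
      standard_id = sprintf("std_%02d", s),
      replicate = seq_len(n_replicates),
      aliquot_ml = aliquot_ml,
      diluent_ml = diluent_ml,
      cpm_ml = noisy(rep(conc_true + bg_cpm_ml, n_replicates)),
      background_cpm_ml = bg_cpm_ml
    )
  })
  list(injections = injections, blood = blood, standards = standards,
       true_tbw_ml = true_tbw_ml)
}

#' Generate a synthetic regression dataset with known parameters
#'
#' Data are drawn exactly under the likelihood of the matching
#' [fit_simple()], [fit_shared_slope()] or [fit_logit_water_fat()] model,
#' including the water-ratio-scaled residuals of the logit model.
#'
#' @param kind `"simple"`, `"shared_slope"` or `"logit"`.
#' @param params Named list of generating parameters:
#'   simple `beta0, beta1, sigma, x_range`;
#'   shared_slope `slope, intercepts` (named vector)`, sigma, x_range`
#'   (`n` is per site);
#'   logit `alpha0, alpha1, sigma, p_h2o_range`.
#' @param n Number of observations (per site for `shared_slope`).
#' @param seed Random seed; generation is a pure function of
#'   (`params`, `n`, `seed`).
#' @return A tibble with the generating parameters attached as
#'   `attr(, "truth")`.
#' @export
#' @examples
#' make_regression("simple", list(beta0 = -18, beta1 = 0.9, sigma = 3),
#'                 n = 14, seed = 7)
make_regression <- function(kind = c("simple", "shared_slope", "logit"),
                            params = list(), n = 20, seed = 1) {
  kind <- match.arg(kind)
  if (n < 3) {
    rlang::abort("Need n >= 3.", class = "pinnicomp_domain_error")
  }
  set.seed(seed)
  out <- switch(kind,
    simple = {
      p <- modifyList(list(beta0 = 0, beta1 = 1, sigma = 1,
                           x_range = c(0, 10)), params)
      x <- stats::runif(n, p$x_range[1], p$x_range[2])
      tibble::tibble(x = x,
                     y = p$beta0 + p$beta1 * x +
                       stats::rnorm(n, 0, p$sigma))
    },
    shared_slope = {
      p <- modifyList(list(slope = 1,
                           intercepts = c(pelvis = 1, umbilicus = 2),
                           sigma = 1, x_range = c(0, 10)), params)
      if (is.null(names(p$intercepts))) {
        rlang::abort("`intercepts` must be a named vector.",
                     class = "pinnicomp_config_error")
      }
      purrr::imap_dfr(p$intercepts, function(b0, s) {
        x <- stats::runif(n, p$x_range[1], p$x_range[2])
        tibble::tibble(site = s, x = x,
                       y = p$slope * x + b0 + stats::rnorm(n, 0, p$sigma))
      })
    },
    logit = {
      p <- modifyList(list(alpha0 = -1.6, alpha1 = -0.86, sigma = 0.3,
                           p_h2o_range = c(0.4, 0.75)), params)
      pw <- stats::runif(n, p$p_h2o_range[1], p$p_h2o_range[2])
      xr <- pw / (1 - pw)
      eta <- p$alpha0 + p$alpha1 * xr + xr * stats::rnorm(n, 0, p$sigma)
      tibble::tibble(p_h2o = pw, p_fat = stats::plogis(eta))
    }
  )
  attr(out, "truth") <- params
  out
}
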