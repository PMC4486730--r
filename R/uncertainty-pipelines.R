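# Measurement-uncertainty pipelines: build input distributions from the
# replicate data of one animal and push them through the modified-cones or
# labeled-water proportion-fat estimator, for whole-pipeline propagation and
# one-at-a-time sensitivity ranking.

# Input distributions for one animal's modified-cones estimate: per-site
# tape measurements are normal over the replicates, ultrasound depths
# lognormal, tissue parameters come from the property set (proportions as
# betas). Mass is fixed (repeated weighings vary less than the scale's
# accuracy).
cones_fat_inputs <- function(animal_data, props = tissue_properties(),
                             phase = c("early", "late")) {
  phase <- match.arg(phase)
  sites <- cone_sites()$site
  interior <- cone_sites()$interior
  inputs <- list()
  add <- function(lst, inp) c(lst, list(inp))
  for (i in seq_along(sites)) {
    s <- sites[i]
    rows <- animal_data[animal_data$site == s, ]
    if (nrow(rows) == 0) {
      rlang::abort(paste0("Missing site: ", s),
                   class = "pinnicomp_schema_error")
    }
    inputs <- add(inputs, distribution_from_replicates(
      rows$height_cm, "normal", paste0("h_", s)))
    inputs <- add(inputs, distribution_from_replicates(
      rows$width_cm, "normal", paste0("w_", s)))
    inputs <- add(inputs, distribution_from_replicates(
      rows$curvilinear_cm, "normal", paste0("lc_", s)))
    if (interior[i]) {
      inputs <- add(inputs, distribution_from_replicates(
        rows$us_dorsal_cm, "lognormal", paste0("usd_", s)))
      inputs <- add(inputs, distribution_from_replicates(
        rows$us_lateral_cm, "lognormal", paste0("usl_", s)))
    }
  }
  inputs <- add(inputs, distribution_from_replicates(
    animal_data$total_length_cm, "normal", "total_length"))
  ms <- function(nm) props[[nm]]
  norm_in <- function(name, v) {
    input_dist(name, if (v[["sd"]] > 0) "normal" else "fixed",
               mean = v[["mean"]], sd = v[["sd"]], value = v[["mean"]])
  }
  beta_in <- function(name, v) {
    input_dist(name, if (v[["sd"]] > 0) "beta" else "fixed",
               mean = v[["mean"]], sd = v[["sd"]], value = v[["mean"]])
  }
  inputs <- add(inputs, norm_in("skin_depth", ms("skin_depth_cm")))
  inputs <- add(inputs, norm_in("blubber_density", ms("blubber_density")))
  inputs <- add(inputs, norm_in("skin_density", ms("skin_density")))
  inputs <- add(inputs, beta_in("fat_in_blubber",
                                ms(paste0("fat_in_blubber_", phase))))
  inputs <- add(inputs, beta_in("fat_in_skin", ms("fat_in_skin")))
  inputs
}

cones_fat_estimator <- function(mass_kg) {
  sites <- cone_sites()$site
  interior <- cone_sites()$interior
  int_sites <- sites[interior]
  force(mass_kg)
  function(...) {
    z <- list(...)
    g <- function(prefix, ss) unlist(z[paste0(prefix, ss)], use.names = FALSE)
    a <- g("w_", sites) / 2
    b <- g("h_", sites) / 2
    lc <- g("lc_", sites)
    us_d <- us_l <- rep(NA_real_, length(sites))
    us_d[interior] <- g("usd_", int_sites)
    us_l[interior] <- g("usl_", int_sites)
    pc <- partition_core(a, b, lc, z$total_length, us_d, us_l, interior,
                         z$skin_depth, "full_body", "image",
                         warn_clamp = FALSE)
    m_b <- pc$v_blubber * z$blubber_density / 1000
    m_d <- pc$v_skin * z$skin_density / 1000
    (m_b * z$fat_in_blubber + m_d * z$fat_in_skin) / mass_kg
  }
}

#' Uncertainty in modified-cones proportion fat, per animal
#'
#' Builds measurement distributions from one animal's replicate
#' morphometrics (normal for tape measurements, lognormal for ultrasound
#' readings, with all replicates treated as independent), adds the tissue
#' parameter distributions (normal densities and depths, beta fat
#' fractions), and propagates everything through the modified-cones
#' proportion-fat estimator by Monte Carlo. Optionally ranks the inputs by
#' one-at-a-time sensitivity.
#'
#' @param data Morphometric tibble with replicates (possibly many animals).
#' @param props A [tissue_properties()] object.
#' @param phase Molt phase.
#' @param n Monte Carlo draws.
#' @param seed Random seed.
#' @param sensitivity If `TRUE`, also compute the per-input
#'   [sensitivity_oat()] ranking (slower).
#' @return A tibble with one row per animal (`prop_fat_mean`, `prop_fat_sd`,
#'   95% interval); with `sensitivity = TRUE`, a `sensitivity` list-column of
#'   per-input output SDs.
#' @export
cones_uncertainty <- function(data, props = tissue_properties(),
                              phase = c("early", "late"),
                              n = 15000, seed = 1, sensitivity = FALSE) {
  phase <- match.arg(phase)
  data |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(function(df, key) {
      inputs <- cones_fat_inputs(df, props, phase)
      est <- cones_fat_estimator(mass_kg = df$mass_kg[1])
      pr <- propagate(est, inputs, n = n, seed = seed)
      out <- tibble::tibble(
        prop_fat_mean = pr$mean, prop_fat_sd = pr$sd,
        ci_lo = pr$ci[1], ci_hi = pr$ci[2],
        failure_fraction = pr$failure_fraction
      )
      if (sensitivity) {
        out$sensitivity <- list(sensitivity_oat(est, inputs, n = n,
                                                seed = seed))
      }
      out
    }) |>
    dplyr::ungroup()
}

#' Uncertainty in labeled-water proportion fat, per animal
#'
#' Propagates count uncertainty (stock specific activity from the standards,
#' equilibrium and background concentrations from the blood replicates, all
#' normal over replicates) together with the water-to-fat conversion
#' uncertainty (joint posterior draws of the logit model, sampled by index
#' so the strong slope-intercept correlation is preserved) into proportion
#' fat. One-at-a-time sensitivity reproduces the ranking of count inputs
#' against the conversion function.
#'
#' @param injections,blood,standards Count tables as in [estimate_tbw()].
#' @param model A `"logit"` [water_fat_model()]; if it carries posterior
#'   draws they define the conversion uncertainty, otherwise the conversion
#'   is treated as fixed.
#' @inheritParams cones_uncertainty
#' @return As [cones_uncertainty()], with `prop_water_mean` and `tbw_ml_mean`
#'   columns added.
#' @export
water_uncertainty <- function(injections, blood, standards,
                              model = water_fat_model("logit"),
                              n = 15000, seed = 1, sensitivity = FALSE) {
  stopifnot(inherits(model, "pc_water_fat_model"), model$kind == "logit")
  stock <- stock_specific_activity(standards)
  draws <- model$draws
  purrr::map_dfr(seq_len(nrow(injections)), function(i) {
    id <- injections$animal_id[i]
    mass <- injections$mass_kg[i]
    inj_g <- injections$injected_g[i]
    eq <- blood$cpm_ml[blood$animal_id == id & blood$role == "equilibrium"]
    bg <- blood$cpm_ml[blood$animal_id == id & blood$role == "background"]
    inputs <- list(
      input_dist("cpm_stock", "normal", mean = stock$mean_cpm_ml,
                 sd = stock$sd_cpm_ml),
      distribution_from_replicates(eq, "normal", "cpm_eq"),
      distribution_from_replicates(bg, "normal", "cpm_bg")
    )
    if (!is.null(draws)) {
      inputs <- c(inputs,
                  list(input_dist("water_fat", "index", k = nrow(draws))))
    }
    est <- function(cpm_stock, cpm_eq, cpm_bg, water_fat = 0) {
      tbw_ml <- tbw(inj_g * cpm_stock, cpm_eq, cpm_bg)
      pw <- proportion_water(tbw_ml, mass)
      x <- pw / (1 - pw)
      if (water_fat >= 1 && !is.null(draws)) {
        a0 <- draws$alpha0[water_fat]
        a1 <- draws$alpha1[water_fat]
      } else {
        a0 <- model$alpha0
        a1 <- model$alpha1
      }
      stats::plogis(a0 + a1 * x)
    }
    pr <- propagate(est, inputs, n = n, seed = seed)
    tbw_pt <- tbw(inj_g * stock$mean_cpm_ml, mean(eq), mean(bg))
    out <- tibble::tibble(
      animal_id = id,
      tbw_ml_mean = tbw_pt,
      prop_water_mean = proportion_water(tbw_pt, mass),
      prop_fat_mean = pr$mean, prop_fat_sd = pr$sd,
      ci_lo = pr$ci[1], ci_hi = pr$ci[2],
      failure_fraction = pr$failure_fraction
    )
    if (sensitivity) {
      out$sensitivity <- list(sensitivity_oat(est, inputs, n = n,
                                              seed = seed))
    }
    out
  })
}
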