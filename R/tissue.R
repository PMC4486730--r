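# Tissue properties and volume-to-mass conversion under the traditional and
# modified truncated-cones parameterizations.
#
# Unit conventions throughout: volumes cm^3 (= mL), masses kg, densities
# g/mL. kg = cm^3 * (g/mL) / 1000.

#' Tissue property set
#'
#' Densities, depths and fat fractions used to convert tissue volumes to
#' masses and fat masses, each with a standard deviation for uncertainty
#' propagation. Defaults are measurements from molting adult female northern
#' elephant seals; the traditional constants are the older literature values
#' (sculp treated as blubber at 0.94 g/mL and 90.3% fat). Override any entry,
#' or load a different species/phase from YAML with [read_tissue_config()].
#'
#' @param ... Named overrides, each a `c(mean =, sd =)` pair or a single
#'   number (sd 0).
#' @return An object of class `pc_tissue_props`: a named list of
#'   `c(mean, sd)` vectors.
#' @export
#' @examples
#' props <- tissue_properties()
#' props$blubber_density
tissue_properties <- function(...) {
  defaults <- list(
    blubber_density          = c(mean = 0.89,  sd = 0.03),   # g/mL
    skin_density             = c(mean = 1.17,  sd = 0.13),   # g/mL
    skin_depth_cm            = c(mean = 1.32,  sd = 0.16),
    fat_in_blubber_early     = c(mean = 0.853, sd = 0.026),
    fat_in_blubber_late      = c(mean = 0.823, sd = 0.031),
    fat_in_skin              = c(mean = 0.161, sd = 0.007),
    traditional_sculp_density = c(mean = 0.94,  sd = 0),     # g/mL
    traditional_fat_fraction  = c(mean = 0.903, sd = 0.003)
  )
  over <- list(...)
  for (nm in names(over)) {
    v <- over[[nm]]
    if (length(v) == 1L) v <- c(mean = unname(v), sd = 0)
    if (!all(c("mean", "sd") %in% names(v))) {
      rlang::abort(paste0("`", nm, "` must be c(mean =, sd =) or one number."),
                   class = "pinnicomp_config_error")
    }
    defaults[[nm]] <- v[c("mean", "sd")]
  }
  validate_tissue_props(defaults)
  structure(defaults, class = "pc_tissue_props")
}

validate_tissue_props <- function(p) {
  dens <- c("blubber_density", "skin_density", "traditional_sculp_density")
  for (nm in dens) {
    if (p[[nm]][["mean"]] <= 0) {
      rlang::abort(paste0(nm, " must be positive."),
                   class = "pinnicomp_config_error")
    }
  }
  prop <- c("fat_in_blubber_early", "fat_in_blubber_late", "fat_in_skin",
            "traditional_fat_fraction")
  for (nm in prop) {
    m <- p[[nm]][["mean"]]
    if (m <= 0 || m >= 1) {
      rlang::abort(paste0(nm, " must lie in (0, 1)."),
                   class = "pinnicomp_config_error")
    }
  }
  invisible(p)
}

#' @export
print.pc_tissue_props <- function(x, ...) {
  cat("<tissue properties>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %.4g (sd %.3g)\n", nm, x[[nm]][["mean"]], x[[nm]][["sd"]]))
  }
  invisible(x)
}

prop_mean <- function(props, name) unname(props[[name]][["mean"]])

#' Skin density from a blubber-and-skin core sample
#'
#' A biopsy core of total depth `d_t` spans skin (depth `d_d`) over blubber.
#' Given the bulk density of the whole core and the density of pure blubber,
#' the skin density follows from a mass balance over the two layers:
#' `rho_d = rho_t + (rho_t - rho_b) * (d_t - d_d) / d_d`.
#'
#' @param rho_t Bulk density of the core (g/mL).
#' @param rho_b Blubber density (g/mL).
#' @param d_t Total core depth (cm).
#' @param d_d Skin depth (cm).
#' @return Skin density (g/mL).
#' @export
#' @examples
#' skin_density_from_core(0.93, 0.89, 4, 1.32)
skin_density_from_core <- function(rho_t, rho_b, d_t, d_d) {
  if (any(d_d <= 0)) {
    rlang::abort("`d_d` must be positive.", class = "pinnicomp_domain_error")
  }
  if (any(d_t < d_d)) {
    rlang::abort("`d_t` must be at least `d_d`.",
                 class = "pinnicomp_domain_error")
  }
  rho_t + (rho_t - rho_b) * (d_t - d_d) / d_d
}

#' Traditional cones composition estimate
#'
#' The traditional method treats everything between the body surface and the
#' muscle boundary (the sculp) as blubber, converts its volume to mass with
#' the literature sculp density, and applies a fixed fat fraction. Skin is
#' not separated.
#'
#' @param data A tibble with columns `v_blubber_cm3` and `mass_kg` (one row
#'   per animal), e.g. from [partition_volumes()] with
#'   `shape = "circular", extent = "neck_to_pelvis", depth_source = "mean"`
#'   and `skin_depth = 0`.
#' @param props A [tissue_properties()] object.
#' @return The input with `blubber_mass_kg`, `fat_mass_kg`, `prop_adipose`
#'   and `prop_fat` columns added.
#' @export
traditional_estimate <- function(data, props = tissue_properties()) {
  check_mass(data$mass_kg)
  check_nonneg(v_blubber_cm3 = data$v_blubber_cm3)
  rho <- prop_mean(props, "traditional_sculp_density")
  ffrac <- prop_mean(props, "traditional_fat_fraction")
  data |>
    dplyr::mutate(
      method = "traditional",
      blubber_mass_kg = .data$v_blubber_cm3 * rho / 1000,
      fat_mass_kg = .data$blubber_mass_kg * ffrac,
      prop_adipose = .data$blubber_mass_kg / .data$mass_kg,
      prop_fat = .data$fat_mass_kg / .data$mass_kg
    )
}

check_mass <- function(m) {
  if (any(!is.finite(m)) || any(m <= 0)) {
    rlang::abort("`mass_kg` must be positive and known for every animal.",
                 class = "pinnicomp_domain_error")
  }
  invisible(m)
}

#' Modified cones composition estimate
#'
#' Converts the skin and blubber shell volumes of a partition to tissue and
#' fat masses using tissue-specific densities and fat fractions measured on
#' elephant seals, keeping skin and blubber separate. Blubber fat fraction
#' differs between the early and late molt.
#'
#' @param data A partition tibble from [partition_volumes()] (needs
#'   `v_skin_cm3`, `v_blubber_cm3`, `v_total_cm3`, `mass_kg`).
#' @param props A [tissue_properties()] object.
#' @param phase Molt phase, `"early"` or `"late"`.
#' @return The input with mass/fat columns added: `blubber_mass_kg`,
#'   `skin_mass_kg`, `blubber_fat_kg`, `skin_fat_kg`, `fat_mass_kg`,
#'   `prop_adipose` (blubber mass over total mass) and `prop_fat`.
#' @export
modified_estimate <- function(data, props = tissue_properties(),
                              phase = c("early", "late")) {
  phase <- match.arg(phase)
  check_mass(data$mass_kg)
  rho_b <- prop_mean(props, "blubber_density")
  rho_d <- prop_mean(props, "skin_density")
  f_b <- prop_mean(props, paste0("fat_in_blubber_", phase))
  f_d <- prop_mean(props, "fat_in_skin")
  data |>
    dplyr::mutate(
      method = "modified", phase = phase,
      blubber_mass_kg = .data$v_blubber_cm3 * rho_b / 1000,
      skin_mass_kg = .data$v_skin_cm3 * rho_d / 1000,
      blubber_fat_kg = .data$blubber_mass_kg * f_b,
      skin_fat_kg = .data$skin_mass_kg * f_d,
      fat_mass_kg = .data$blubber_fat_kg + .data$skin_fat_kg,
      prop_adipose = .data$blubber_mass_kg / .data$mass_kg,
      prop_fat = .data$fat_mass_kg / .data$mass_kg
    )
}

#' Total body density
#'
#' Measured total mass divided by truncated-cone body volume.
#'
#' @param mass_kg Total mass (kg).
#' @param v_total_cm3 Body volume (cm^3).
#' @return Density in g/mL.
#' @export
total_body_density <- function(mass_kg, v_total_cm3) {
  if (any(v_total_cm3 <= 0)) {
    rlang::abort("`v_total_cm3` must be positive.",
                 class = "pinnicomp_domain_error")
  }
  1000 * mass_kg / v_total_cm3
}

#' Density of the non-blubber body (core plus skin)
#'
#' Removes the blubber shell's mass and volume from the whole body and
#' reports the density of what remains.
#'
#' @param data A partition tibble with `mass_kg`, `v_total_cm3` and
#'   `v_blubber_cm3`.
#' @param props A [tissue_properties()] object (for blubber density).
#' @return The input with a `non_blubber_density` column (g/mL) added.
#' @export
non_blubber_density <- function(data, props = tissue_properties()) {
  rho_b <- prop_mean(props, "blubber_density")
  m_b <- data$v_blubber_cm3 * rho_b / 1000
  num <- data$mass_kg - m_b
  den <- data$v_total_cm3 - data$v_blubber_cm3
  if (any(num <= 0) || any(den <= 0)) {
    rlang::abort(
      "Blubber mass/volume meets or exceeds the whole body; inconsistent inputs.",
      class = "pinnicomp_inconsistency"
    )
  }
  dplyr::mutate(data, non_blubber_density = 1000 * num / den)
}

#' Bulk properties of the sculp (skin + blubber)
#'
#' Volume-weighted density and mass-weighted fat fraction of the combined
#' skin-and-blubber layer, the tissue an ultrasound depth actually spans.
#'
#' @inheritParams modified_estimate
#' @return The input with `sculp_density` (g/mL) and `sculp_fat_fraction`
#'   columns added.
#' @export
sculp_summary <- function(data, props = tissue_properties(),
                          phase = c("early", "late")) {
  phase <- match.arg(phase)
  v_sculp <- data$v_skin_cm3 + data$v_blubber_cm3
  if (any(v_sculp <= 0)) {
    rlang::abort("Sculp volume is zero; nothing to summarise.",
                 class = "pinnicomp_domain_error")
  }
  rho_b <- prop_mean(props, "blubber_density")
  rho_d <- prop_mean(props, "skin_density")
  f_b <- prop_mean(props, paste0("fat_in_blubber_", phase))
  f_d <- prop_mean(props, "fat_in_skin")
  m_b <- data$v_blubber_cm3 * rho_b / 1000
  m_d <- data$v_skin_cm3 * rho_d / 1000
  dplyr::mutate(
    data,
    sculp_density = 1000 * (m_b + m_d) / v_sculp,
    sculp_fat_fraction = (m_b * f_b + m_d * f_d) / (m_b + m_d)
  )
}
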