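# Cross-instrument ultrasound calibration: converting sculp depths read from
# a non-imaging device to image-equivalent depths via a shared-slope,
# per-site-intercept linear model.

#' Construct an ultrasound calibration
#'
#' Relates sculp depth read from a non-imaging ultrasound (`x`) to the depth
#' measured on a digital image at the same site: `y = slope * x +
#' intercept[site]`. The slope is shared across body sites; intercepts are
#' site-specific. Optionally carries joint posterior draws of the parameters
#' from [fit_shared_slope()].
#'
#' @param slope Shared slope (dimensionless).
#' @param intercepts Named numeric vector of per-site intercepts (cm); names
#'   must be landmark sites.
#' @param sigma2 Residual variance (cm^2).
#' @param surface `"dorsal"` or `"lateral"`.
#' @param draws Optional tibble of posterior draws with columns `slope` and
#'   one column per intercept name.
#' @return An object of class `pc_us_calibration`.
#' @export
ultrasound_calibration <- function(slope, intercepts, sigma2 = 0,
                                   surface = c("dorsal", "lateral"),
                                   draws = NULL) {
  surface <- match.arg(surface)
  site_order(names(intercepts))  # validates names
  structure(
    list(slope = slope, intercepts = intercepts, sigma2 = sigma2,
         surface = surface, draws = draws),
    class = "pc_us_calibration"
  )
}

#' Default ultrasound calibrations
#'
#' Point calibrations (posterior marginal means) for converting non-imaging
#' sculp-depth readings to image-equivalent depths, for each probe surface.
#' Intercept units are centimetres.
#'
#' @param surface `"dorsal"` or `"lateral"`.
#' @return A `pc_us_calibration` object.
#' @export
#' @examples
#' default_ultrasound_calibration("dorsal")$slope
default_ultrasound_calibration <- function(surface = c("dorsal", "lateral")) {
  surface <- match.arg(surface)
  if (surface == "dorsal") {
    ultrasound_calibration(
      slope = 0.873,
      intercepts = c(pelvis = 1.26, umbilicus = 0.933, mid = 0.851,
                     sternum = 0.841, axilla = 0.827, neck = 0.540),
      sigma2 = 2.12e-3, surface = "dorsal"
    )
  } else {
    ultrasound_calibration(
      slope = 0.583,
      intercepts = c(pelvis = 1.95, umbilicus = 2.13, mid = 2.15,
                     sternum = 2.21, axilla = 2.23, neck = 2.00),
      sigma2 = 1.24e-3, surface = "lateral"
    )
  }
}

#' @export
print.pc_us_calibration <- function(x, ...) {
  cat(sprintf("<ultrasound calibration, %s surface>\n", x$surface))
  cat(sprintf("  slope %.4g, residual variance %.3g\n", x$slope, x$sigma2))
  cat("  intercepts (cm):\n")
  print(round(x$intercepts, 4))
  if (!is.null(x$draws)) {
    cat(sprintf("  with %d posterior draws\n", nrow(x$draws)))
  }
  invisible(x)
}

#' Convert a non-image sculp depth to its image-equivalent value
#'
#' @param x Non-image depth reading(s), cm.
#' @param site Landmark site of the reading (recycled against `x`).
#' @param calibration A [ultrasound_calibration()] object.
#' @param posterior If `TRUE` and the calibration carries posterior draws,
#'   return the induced distribution (a tibble with one row per input x draw)
#'   instead of the point conversion.
#' @return Numeric vector of converted depths (cm), or a tibble of draws.
#' @export
#' @examples
#' convert_ultrasound_depth(2, "pelvis", default_ultrasound_calibration("dorsal"))
convert_ultrasound_depth <- function(x, site, calibration, posterior = FALSE) {
  stopifnot(inherits(calibration, "pc_us_calibration"))
  site <- rep_len(site, length(x))
  unknown <- setdiff(unique(site), names(calibration$intercepts))
  if (length(unknown)) {
    rlang::abort(paste0("No calibration intercept for site(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "pinnicomp_unknown_site")
  }
  if (posterior) {
    if (is.null(calibration$draws)) {
      rlang::abort("Calibration has no posterior draws.",
                   class = "pinnicomp_no_draws")
    }
    d <- calibration$draws
    return(purrr::map2_dfr(x, site, function(xi, si) {
      tibble::tibble(
        x = xi, site = si, draw = seq_len(nrow(d)),
        depth_cm = d$slope * xi + d[[si]]
      )
    }))
  }
  calibration$slope * x + unname(calibration$intercepts[site])
}
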