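# Truncated-cones geometry: segment volumes from landmark morphometrics and
# the skin/blubber/core shell partition.

#' Landmark measurement sites
#'
#' The eight girth locations along a seal's body, ordered from the posterior
#' (ankles) to the anterior (ears). Ultrasound sculp depths are taken at the
#' six interior sites only.
#'
#' @return A tibble with columns `site`, `order` (1 = ankles, 8 = ears) and
#'   `interior` (logical; `TRUE` where ultrasound depths exist).
#' @export
#' @examples
#' cone_sites()
cone_sites <- function() {
  tibble::tibble(
    site = c("ankles", "pelvis", "umbilicus", "mid",
             "sternum", "axilla", "neck", "ears"),
    order = 1:8,
    interior = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
}

site_order <- function(site) {
  ord <- match(site, cone_sites()$site)
  if (anyNA(ord)) {
    rlang::abort(
      paste0("Unknown site(s): ",
             paste(unique(site[is.na(ord)]), collapse = ", ")),
      class = "pinnicomp_unknown_site"
    )
  }
  ord
}

#' Straight length between two girth stations
#'
#' Curvilinear length is measured along the animal's surface; the axial
#' (straight) length of a body segment is recovered from the curvilinear
#' length and the difference in radii at its two ends, treating the surface
#' path as the hypotenuse of a right triangle.
#'
#' @param l_c Curvilinear length between the stations (cm).
#' @param r1,r2 Radii (or height semi-axes) at the two ends (cm).
#' @return Straight length (cm), always `<= l_c`.
#' @export
#' @examples
#' straight_length(5, 4, 1)   # 3-4-5 triangle -> 4
#' straight_length(10, 3, 3)  # equal radii -> 10
straight_length <- function(l_c, r1, r2) {
  dr <- abs(r1 - r2)
  bad <- l_c <= dr
  if (any(bad)) {
    rlang::abort(
      sprintf(
        "Degenerate segment: curvilinear length (%s) must exceed the radius difference (%s).",
        paste(signif(l_c[bad], 5), collapse = ", "),
        paste(signif(dr[bad], 5), collapse = ", ")
      ),
      class = "pinnicomp_degenerate_segment"
    )
  }
  sqrt(l_c^2 - dr^2)
}

#' Volume of an elliptical truncated cone (frustum)
#'
#' Cross-sections are ellipses with semi-axes interpolated linearly between
#' the two ends; the closed form is the exact integral of the elliptical
#' cross-sectional area along the segment.
#'
#' @param a1,b1 Semi-axes at one end (cm): `a` horizontal (width/2), `b`
#'   vertical (height/2).
#' @param a2,b2 Semi-axes at the other end (cm).
#' @param l_s Straight (axial) segment length (cm).
#' @return Volume in cm^3. With `a = b = r` at each end this reduces to the
#'   circular frustum.
#' @export
#' @examples
#' frustum_volume(1, 1, 1, 1, 3)  # unit-circle cylinder: 3 * pi
frustum_volume <- function(a1, b1, a2, b2, l_s) {
  check_nonneg(a1 = a1, b1 = b1, a2 = a2, b2 = b2, l_s = l_s)
  (pi * l_s / 6) * (2 * a1 * b1 + a2 * b1 + b2 * a1 + 2 * a2 * b2)
}

#' Volume of an elliptical end cone
#'
#' Used for the nose and tail ends of a full-body volume, where the body
#' tapers from an elliptical cross-section to a point.
#'
#' @param a,b Semi-axes of the base ellipse (cm).
#' @param l_s Straight length from base to tip (cm).
#' @return Volume in cm^3 (`pi * l_s * a * b / 3`).
#' @export
end_cone_volume <- function(a, b, l_s) {
  check_nonneg(a = a, b = b, l_s = l_s)
  pi * l_s * a * b / 3
}

check_nonneg <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    if (any(args[[nm]] < 0, na.rm = TRUE)) {
      rlang::abort(paste0("`", nm, "` must be non-negative."),
                   class = "pinnicomp_domain_error")
    }
    if (anyNA(args[[nm]])) {
      rlang::abort(paste0("`", nm, "` contains missing values."),
                   class = "pinnicomp_domain_error")
    }
  }
  invisible(NULL)
}

#' Average replicate measurements per animal and site
#'
#' Triplicate observer measurements are reduced to per-site means before any
#' geometry; the raw replicates remain available for uncertainty analysis.
#'
#' @param data A morphometric tibble with one row per
#'   animal x replicate x site (see [read_morphometrics()] for the schema).
#' @return One row per animal x site with replicate means and `n_replicates`.
#' @export
summarise_replicates <- function(data) {
  meas <- intersect(
    c("girth_cm", "height_cm", "width_cm", "curvilinear_cm",
      "us_dorsal_cm", "us_lateral_cm", "total_length_cm", "mass_kg"),
    names(data)
  )
  data |>
    dplyr::group_by(.data$animal_id, .data$site) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(meas), ~ mean(.x, na.rm = TRUE)),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}

# Build the ordered per-site geometry table for one animal.
# Returns site, a, b (outer semi-axes, cm), lc, plus depths if present.
site_table <- function(df, shape) {
  df <- df[order(site_order(df$site)), , drop = FALSE]
  if (anyDuplicated(df$site)) {
    rlang::abort("Duplicate site rows for one animal; average replicates first.",
                 class = "pinnicomp_schema_error")
  }
  if (shape == "elliptical") {
    need <- c("height_cm", "width_cm")
    miss <- need[!need %in% names(df) | vapply(need, function(v) anyNA(df[[v]]), TRUE)]
    if (length(miss)) {
      rlang::abort(paste0("Elliptical shape requires complete ",
                          paste(miss, collapse = ", "), "."),
                   class = "pinnicomp_schema_error")
    }
    df$a <- df$width_cm / 2
    df$b <- df$height_cm / 2
  } else {
    if (!"girth_cm" %in% names(df) || anyNA(df$girth_cm)) {
      rlang::abort("Circular shape requires complete girth_cm.",
                   class = "pinnicomp_schema_error")
    }
    df$a <- df$b <- df$girth_cm / (2 * pi)
  }
  df$lc <- df$curvilinear_cm
  if (is.unsorted(df$lc, strictly = TRUE)) {
    rlang::abort("curvilinear_cm must increase strictly from ankles to ears.",
                 class = "pinnicomp_schema_error")
  }
  df
}

# Keep only the sites an extent needs, in posterior->anterior order.
extent_sites <- function(st, extent) {
  if (extent == "neck_to_pelvis") {
    keep <- st$site %in% cone_sites()$site[cone_sites()$interior]
    st <- st[keep, , drop = FALSE]
  }
  need <- if (extent == "neck_to_pelvis") {
    cone_sites()$site[cone_sites()$interior]
  } else {
    cone_sites()$site
  }
  miss <- setdiff(need, st$site)
  if (length(miss)) {
    rlang::abort(paste0("Missing site measurement(s): ",
                        paste(miss, collapse = ", ")),
                 class = "pinnicomp_schema_error")
  }
  st
}

# Straight lengths along a stack of sites (from outer geometry) plus, for the
# full body, the two end-cone axial lengths. The same axial lengths are used
# for every concentric shell: the body axis does not move when a tissue
# boundary is eroded inward.
axial_lengths <- function(st, extent, total_length = NULL) {
  n <- nrow(st)
  seg <- straight_length(diff(st$lc), st$b[-n], st$b[-1])
  cones <- NULL
  if (extent == "full_body") {
    post <- straight_length(st$lc[1], st$b[1], 0)
    if (is.null(total_length) || is.na(total_length)) {
      rlang::abort("Full-body extent requires total_length_cm.",
                   class = "pinnicomp_schema_error")
    }
    ant <- straight_length(total_length - st$lc[n], st$b[n], 0)
    cones <- list(posterior = post, anterior = ant)
  }
  list(segments = seg, cones = cones)
}

# Volume of a stack of frusta (+ optional end cones) given per-site semi-axes.
stack_volume <- function(a, b, ax) {
  n <- length(a)
  segs <- frustum_volume(a[-n], b[-n], a[-1], b[-1], ax$segments)
  v <- sum(segs)
  cone_post <- cone_ant <- 0
  if (!is.null(ax$cones)) {
    cone_post <- end_cone_volume(a[1], b[1], ax$cones$posterior)
    cone_ant <- end_cone_volume(a[n], b[n], ax$cones$anterior)
    v <- v + cone_post + cone_ant
  }
  list(total = v, segments = segs, cone_posterior = cone_post,
       cone_anterior = cone_ant)
}

#' Whole-body or trunk volume from morphometrics
#'
#' Sums elliptical (or circular) frustum volumes between adjacent landmark
#' sites. The full-body extent adds a posterior end cone (tail to ankles) and
#' an anterior end cone (ears to nose tip); the neck-to-pelvis extent covers
#' only the trunk segments used by the traditional method.
#'
#' @param data Morphometric tibble (raw replicates or already averaged).
#' @param shape `"elliptical"` (uses heights and widths) or `"circular"`
#'   (radius from girth as G/(2*pi)).
#' @param extent `"full_body"` or `"neck_to_pelvis"`.
#' @return A tibble with one row per animal: `volume_cm3`, `mass_kg` (if
#'   present) and a `segments` list-column of per-segment volumes.
#' @export
body_volume <- function(data,
                        shape = c("elliptical", "circular"),
                        extent = c("full_body", "neck_to_pelvis")) {
  shape <- match.arg(shape)
  extent <- match.arg(extent)
  if ("replicate" %in% names(data)) data <- summarise_replicates(data)
  data |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(function(df, key) {
      st <- extent_sites(site_table(df, shape), extent)
      ax <- axial_lengths(st, extent, total_length = df$total_length_cm[1])
      sv <- stack_volume(st$a, st$b, ax)
      seg_tbl <- tibble::tibble(
        from = st$site[-nrow(st)], to = st$site[-1],
        straight_cm = ax$segments, volume_cm3 = sv$segments
      )
      tibble::tibble(
        shape = shape, extent = extent,
        volume_cm3 = sv$total,
        cone_posterior_cm3 = sv$cone_posterior,
        cone_anterior_cm3 = sv$cone_anterior,
        mass_kg = if ("mass_kg" %in% names(df)) df$mass_kg[1] else NA_real_,
        segments = list(seg_tbl)
      )
    }) |>
    dplyr::ungroup()
}

# Numeric core of the partition for one animal: vectors ordered
# posterior -> anterior over the extent's sites. `interior` marks sites with
# ultrasound depths; at the others the inner boundary coincides with the
# skin boundary. Cheap on purpose: the Monte Carlo engine calls it once per
# draw.
partition_core <- function(a, b, lc, total_length, us_d, us_l, interior,
                           skin_depth, extent, depth_source,
                           warn_clamp = TRUE) {
  if (skin_depth >= min(a, b)) {
    rlang::abort("`skin_depth` meets or exceeds the smallest semi-axis.",
                 class = "pinnicomp_degenerate_body")
  }
  n <- length(a)
  seg <- straight_length(diff(lc), b[-n], b[-1])
  cones <- NULL
  if (extent == "full_body") {
    cones <- list(posterior = straight_length(lc[1], b[1], 0),
                  anterior = straight_length(total_length - lc[n], b[n], 0))
  }
  ax <- list(segments = seg, cones = cones)
  a_skin <- a - skin_depth
  b_skin <- b - skin_depth
  if (depth_source == "mean") {
    d <- (us_d + us_l) / 2
    a_dep <- b_dep <- d
  } else {
    a_dep <- us_l
    b_dep <- us_d
  }
  a_in <- ifelse(interior, a - a_dep, a_skin)
  b_in <- ifelse(interior, b - b_dep, b_skin)
  n_clamped <- sum(a_in < 0) + sum(b_in < 0)
  if (n_clamped > 0) {
    if (warn_clamp) {
      rlang::warn(sprintf("%d inner semi-ax(es) clamped at zero.", n_clamped),
                  class = "pinnicomp_clamped")
    }
    a_in <- pmax(a_in, 0)
    b_in <- pmax(b_in, 0)
  }
  # sculp depth can never be shallower than the skin itself
  a_in <- pmin(a_in, a_skin)
  b_in <- pmin(b_in, b_skin)
  v_total <- stack_volume(a, b, ax)$total
  v_minus_skin <- stack_volume(a_skin, b_skin, ax)$total
  v_inner <- stack_volume(a_in, b_in, ax)$total
  list(v_total = v_total,
       v_skin = v_total - v_minus_skin,
       v_blubber = v_minus_skin - v_inner,
       v_core = v_inner,
       n_clamped = n_clamped)
}

#' Partition body volume into skin, blubber and core shells
#'
#' Three nested volumes are computed from the same axial geometry: the outer
#' surface, the surface eroded by skin depth, and the surface eroded by the
#' ultrasound sculp depth (skin + blubber). Differences give the skin shell,
#' the blubber shell, and the core. Dorsal sculp depth is subtracted from the
#' vertical semi-axis and lateral depth from the horizontal semi-axis
#' (`depth_source = "image"`); the traditional variant subtracts the mean of
#' the available depths from both axes (`depth_source = "mean"`). At the ears
#' and ankles the inner boundary coincides with the skin boundary, so blubber
#' tapers to zero beyond the instrumented sites, and the end cones contain
#' skin and core only.
#'
#' @inheritParams body_volume
#' @param skin_depth Uniform skin thickness (cm).
#' @param depth_source `"image"` (dorsal/lateral applied to their own axes) or
#'   `"mean"` (single mean depth on both axes).
#' @return A tibble with one row per animal: `v_total_cm3`, `v_skin_cm3`,
#'   `v_blubber_cm3`, `v_core_cm3`, `n_clamped` (inner semi-axes clamped at
#'   zero), `mass_kg`, plus the shape/extent used. Components always sum to
#'   the total.
#' @export
partition_volumes <- function(data,
                              skin_depth,
                              shape = c("elliptical", "circular"),
                              extent = c("full_body", "neck_to_pelvis"),
                              depth_source = c("image", "mean")) {
  shape <- match.arg(shape)
  extent <- match.arg(extent)
  depth_source <- match.arg(depth_source)
  if (skin_depth < 0) {
    rlang::abort("`skin_depth` must be non-negative.",
                 class = "pinnicomp_domain_error")
  }
  if ("replicate" %in% names(data)) data <- summarise_replicates(data)
  data |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(function(df, key) {
      st <- extent_sites(site_table(df, shape), extent)
      interior <- st$site %in% cone_sites()$site[cone_sites()$interior]
      if (any(interior & (is.na(st$us_dorsal_cm) | is.na(st$us_lateral_cm)))) {
        rlang::abort("Sculp depths required at all interior sites.",
                     class = "pinnicomp_schema_error")
      }
      pc <- partition_core(
        st$a, st$b, st$lc, df$total_length_cm[1],
        st$us_dorsal_cm, st$us_lateral_cm, interior,
        skin_depth, extent, depth_source
      )
      tibble::tibble(
        shape = shape, extent = extent, depth_source = depth_source,
        v_total_cm3 = pc$v_total,
        v_skin_cm3 = pc$v_skin,
        v_blubber_cm3 = pc$v_blubber,
        v_core_cm3 = pc$v_core,
        n_clamped = pc$n_clamped,
        mass_kg = if ("mass_kg" %in% names(df)) df$mass_kg[1] else NA_real_
      )
    }) |>
    dplyr::ungroup()
}
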