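# Readers/writers for the tab-delimited data schemas and YAML configs.
# Readers validate rather than coerce: malformed cells are reported with
# their row and column.

#' Default schema configuration for the tabular readers
#'
#' Maps the logical column names the package uses onto the column names in a
#' file, declares the depth unit, and lists site-name aliases. Override any
#' part, or load a YAML file with the same structure via
#' [read_schema_config()].
#'
#' @param columns Named list or vector: logical name -> file column name.
#' @param depth_unit `"cm"` or `"mm"` for the ultrasound depth columns.
#' @param site_aliases Named character vector mapping file site names to the
#'   canonical names of [cone_sites()].
#' @return A list of class `pc_schema`.
#' @export
schema_config <- function(columns = list(), depth_unit = c("cm", "mm"),
                          site_aliases = c(axial = "axilla",
                                           `mid-seal` = "mid")) {
  depth_unit <- match.arg(depth_unit)
  logical_cols <- c("animal_id", "replicate", "site", "girth_cm",
                    "height_cm", "width_cm", "curvilinear_cm",
                    "us_dorsal_cm", "us_lateral_cm", "total_length_cm",
                    "mass_kg", "sample_id", "role", "cpm_ml", "volume_ml",
                    "aliquot_ml", "diluent_ml", "background_cpm_ml",
                    "injected_g")
  mapping <- stats::setNames(as.list(logical_cols), logical_cols)
  for (nm in names(columns)) {
    if (!nm %in% logical_cols) {
      rlang::abort(paste0("Unknown logical column `", nm, "`."),
                   class = "pinnicomp_config_error")
    }
    mapping[[nm]] <- columns[[nm]]
  }
  structure(list(columns = mapping, depth_unit = depth_unit,
                 site_aliases = site_aliases),
            class = "pc_schema")
}

#' Read a schema configuration from YAML
#'
#' @param path YAML file with optional keys `columns`, `depth_unit`,
#'   `site_aliases`.
#' @return A `pc_schema` list.
#' @export
read_schema_config <- function(path) {
  y <- yaml::read_yaml(path)
  schema_config(
    columns = y$columns %||% list(),
    depth_unit = y$depth_unit %||% "cm",
    site_aliases = unlist(y$site_aliases) %||%
      c(axial = "axilla", `mid-seal` = "mid")
  )
}

read_tsv_raw <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("File not found: ", path),
                 class = "pinnicomp_io_error")
  }
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

# rename file columns -> logical names; error if a required one is absent
apply_schema <- function(df, schema, required, optional = character()) {
  for (lg in c(required, optional)) {
    file_col <- schema$columns[[lg]]
    if (is.null(file_col) || !file_col %in% names(df)) {
      if (lg %in% required) {
        rlang::abort(paste0("Missing mapped column `", file_col %||% lg,
                            "` (logical `", lg, "`)."),
                     class = "pinnicomp_schema_error")
      }
      next
    }
    names(df)[names(df) == file_col] <- lg
  }
  df
}

# strict numeric conversion with row-numbered error reporting
to_numeric <- function(df, cols, allow_na = character()) {
  for (cl in intersect(cols, names(df))) {
    raw <- df[[cl]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & raw != "" & raw != "NA")
    if (length(bad)) {
      rlang::abort(sprintf("Non-numeric value in column `%s`, row(s) %s.",
                           cl, paste(head(bad, 5), collapse = ", ")),
                   class = "pinnicomp_row_error")
    }
    if (!cl %in% allow_na && anyNA(num)) {
      bad_na <- which(is.na(num))
      rlang::abort(sprintf("Missing value in column `%s`, row(s) %s.",
                           cl, paste(head(bad_na, 5), collapse = ", ")),
                   class = "pinnicomp_row_error")
    }
    df[[cl]] <- num
  }
  df
}

check_positive_rows <- function(df, cols) {
  for (cl in intersect(cols, names(df))) {
    bad <- which(!is.na(df[[cl]]) & df[[cl]] <= 0)
    if (length(bad)) {
      rlang::abort(sprintf("Non-positive value in column `%s`, row(s) %s.",
                           cl, paste(head(bad, 5), collapse = ", ")),
                   class = "pinnicomp_row_error")
    }
  }
  invisible(df)
}

#' Read a morphometric measurement table
#'
#' Tab-delimited, one row per animal x replicate x site. Validates numeric
#' cells, positivity, canonical site names (after aliasing) and that
#' curvilinear length increases from ankles to ears within each
#' animal x replicate.
#'
#' @param path File path.
#' @param schema A [schema_config()].
#' @return A validated tibble in the package's logical schema (depths in
#'   cm).
#' @export
read_morphometrics <- function(path, schema = schema_config()) {
  df <- read_tsv_raw(path)
  df <- apply_schema(
    df, schema,
    required = c("animal_id", "replicate", "site", "girth_cm", "height_cm",
                 "width_cm", "curvilinear_cm", "total_length_cm", "mass_kg"),
    optional = c("us_dorsal_cm", "us_lateral_cm")
  )
  alias <- schema$site_aliases
  hit <- df$site %in% names(alias)
  df$site[hit] <- unname(alias[df$site[hit]])
  site_order(df$site)
  df <- to_numeric(
    df,
    c("replicate", "girth_cm", "height_cm", "width_cm", "curvilinear_cm",
      "us_dorsal_cm", "us_lateral_cm", "total_length_cm", "mass_kg"),
    allow_na = c("us_dorsal_cm", "us_lateral_cm")
  )
  check_positive_rows(df, c("girth_cm", "height_cm", "width_cm",
                            "curvilinear_cm", "total_length_cm", "mass_kg"))
  if (schema$depth_unit == "mm") {
    df$us_dorsal_cm <- df$us_dorsal_cm / 10
    df$us_lateral_cm <- df$us_lateral_cm / 10
  }
  bad <- df |>
    dplyr::group_by(.data$animal_id, .data$replicate) |>
    dplyr::arrange(site_order(.data$site), .by_group = TRUE) |>
    dplyr::summarise(ok = !is.unsorted(.data$curvilinear_cm, strictly = TRUE),
                     .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad)) {
    rlang::abort(paste0(
      "curvilinear_cm not strictly increasing for animal/replicate: ",
      paste(bad$animal_id, bad$replicate, sep = "/", collapse = ", ")),
      class = "pinnicomp_row_error")
  }
  dplyr::as_tibble(df)
}

#' Read a scintillation count table
#'
#' Tab-delimited count data with a `role` column distinguishing
#' `equilibrium`, `background` and `standard` rows. Standard rows carry the
#' dilution geometry (`aliquot_ml`, `diluent_ml`).
#'
#' @inheritParams read_morphometrics
#' @return A list of tibbles: `blood` (equilibrium/background rows) and
#'   `standards`.
#' @export
read_counts <- function(path, schema = schema_config()) {
  df <- read_tsv_raw(path)
  df <- apply_schema(
    df, schema,
    required = c("sample_id", "replicate", "role", "cpm_ml"),
    optional = c("animal_id", "aliquot_ml", "diluent_ml",
                 "background_cpm_ml")
  )
  ok_roles <- c("equilibrium", "background", "standard")
  bad <- which(!df$role %in% ok_roles)
  if (length(bad)) {
    rlang::abort(sprintf("Unknown role in row(s) %s (expected %s).",
                         paste(head(bad, 5), collapse = ", "),
                         paste(ok_roles, collapse = "/")),
                 class = "pinnicomp_row_error")
  }
  df <- to_numeric(df, c("replicate", "cpm_ml", "aliquot_ml", "diluent_ml",
                         "background_cpm_ml"),
                   allow_na = c("aliquot_ml", "diluent_ml",
                                "background_cpm_ml"))
  neg <- which(df$cpm_ml < 0)
  if (length(neg)) {
    rlang::abort(sprintf("Negative CPM in row(s) %s.",
                         paste(head(neg, 5), collapse = ", ")),
                 class = "pinnicomp_row_error")
  }
  std <- dplyr::filter(df, .data$role == "standard")
  if (nrow(std) && (anyNA(std$aliquot_ml) || anyNA(std$diluent_ml))) {
    rlang::abort("Standard rows need aliquot_ml and diluent_ml.",
                 class = "pinnicomp_row_error")
  }
  list(
    blood = dplyr::as_tibble(dplyr::filter(df, .data$role != "standard")),
    standards = dplyr::as_tibble(
      dplyr::rename(std, standard_id = "sample_id"))
  )
}

#' Write tables in the package's tab-delimited schemas
#'
#' @param data A tibble.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_morphometrics <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(data)
}

#' @rdname write_morphometrics
#' @export
write_counts <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(data)
}

#' Read tissue properties from a YAML config
#'
#' The YAML mirrors [tissue_properties()]: one key per property, each with
#' `mean` and `sd` entries (a bare number means sd 0).
#'
#' @param path YAML file path.
#' @return A `pc_tissue_props` object.
#' @export
read_tissue_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- purrr::map(y, function(v) {
    if (is.list(v)) c(mean = v$mean, sd = v$sd %||% 0) else v
  })
  do.call(tissue_properties, args)
}

#' @rdname read_tissue_config
#' @param props A `pc_tissue_props` object to serialise.
#' @export
write_tissue_config <- function(props, path) {
  y <- purrr::map(unclass(props),
                  function(v) list(mean = unname(v[["mean"]]),
                                   sd = unname(v[["sd"]])))
  yaml::write_yaml(y, path)
  invisible(props)
}
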