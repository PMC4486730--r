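# Labeled-water (isotope dilution) body composition: total body water from
# scintillation counts and three water-to-fat conversion models.

#' Specific activity of the labeled-water stock from standard dilutions
#'
#' The injectate is too concentrated to count directly, so small aliquots are
#' diluted into known volumes of water and counted. Each replicate count is
#' back-scaled by its dilution factor; the stock activity is summarised as a
#' normal distribution over all replicates.
#'
#' @param standards A tibble with one row per standard x replicate and
#'   columns `aliquot_ml`, `diluent_ml`, `cpm_ml` and (optionally)
#'   `background_cpm_ml` (default 0).
#' @return A one-row tibble: `mean_cpm_ml`, `sd_cpm_ml`, `n`.
#' @export
#' @examples
#' stock_specific_activity(tibble::tibble(
#'   aliquot_ml = 0.01, diluent_ml = 1000, cpm_ml = c(199, 201)
#' ))
stock_specific_activity <- function(standards) {
  need <- c("aliquot_ml", "diluent_ml", "cpm_ml")
  miss <- setdiff(need, names(standards))
  if (length(miss)) {
    rlang::abort(paste0("Standards table missing column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "pinnicomp_schema_error")
  }
  bg <- standards[["background_cpm_ml"]] %||% 0
  if (any(standards$aliquot_ml <= 0)) {
    rlang::abort("`aliquot_ml` must be positive.",
                 class = "pinnicomp_domain_error")
  }
  net <- standards$cpm_ml - bg
  if (any(net <= 0)) {
    rlang::abort("Net standard activity must be positive (count <= background).",
                 class = "pinnicomp_counting_error")
  }
  stock <- net * (standards$diluent_ml + standards$aliquot_ml) /
    standards$aliquot_ml
  tibble::tibble(
    mean_cpm_ml = mean(stock),
    sd_cpm_ml = if (length(stock) > 1) stats::sd(stock) else 0,
    n = length(stock)
  )
}

#' Total body water by isotope dilution
#'
#' At equilibrium the tracer is uniformly diluted in the body water pool, so
#' the pool volume is the injected activity divided by the net equilibrium
#' concentration: `TBW = CPM_inj / (eq - bg)`.
#'
#' @param cpm_inj Total injected activity (CPM); typically injected mass (g)
#'   times stock specific activity (CPM/mL), taking the saline as 1 g/mL.
#' @param eq_cpm_ml Equilibrium specific activity concentration (CPM/mL).
#' @param bg_cpm_ml Background concentration (CPM/mL).
#' @return Total body water in mL.
#' @export
#' @examples
#' tbw(1e6, 100, 0)  # 10,000 mL
tbw <- function(cpm_inj, eq_cpm_ml, bg_cpm_ml = 0) {
  if (any(eq_cpm_ml <= bg_cpm_ml)) {
    rlang::abort("Equilibrium activity must exceed background (no signal).",
                 class = "pinnicomp_no_signal"
    )
  }
  cpm_inj / (eq_cpm_ml - bg_cpm_ml)
}

#' Proportion of body mass that is water
#'
#' @param tbw_ml Total body water (mL; water taken as 1 g/mL).
#' @param mass_kg Total body mass (kg).
#' @return Proportion water in (0, 1).
#' @export
proportion_water <- function(tbw_ml, mass_kg) {
  if (any(tbw_ml < 0)) {
    rlang::abort("`tbw_ml` must be non-negative.",
                 class = "pinnicomp_domain_error")
  }
  p <- tbw_ml / (1000 * mass_kg)
  if (any(p >= 1)) {
    rlang::abort("Total body water meets or exceeds body mass; inconsistent.",
                 class = "pinnicomp_inconsistency")
  }
  p
}

#' Water-to-fat conversion model
#'
#' Bundles the parameters of one of the three conversion rules:
#' * `"logit"`: `logit(P_fat) = alpha0 + alpha1 * x + x * eps`, with
#'   `x = P_H2O / (1 - P_H2O)` the water ratio and residual SD growing with
#'   `x` (heteroscedastic); keeps fat strictly inside (0, 1).
#' * `"iverson"`: linear, `P_fat = 1 - 1.37 * P_H2O`; can go negative.
#' * `"pace_rathbun"`: tissue-water bookkeeping via the water fractions of
#'   adipose (`w_a`) and non-adipose (`w_l`) tissue and the fat fraction of
#'   adipose tissue (`f_a`), with the dilution-vs-carcass water bias
#'   adjustment (0.967).
#'
#' @param kind Model kind.
#' @param alpha0,alpha1,sigma2 Logit parameters (ignored otherwise).
#' @param coef Linear coefficient for `"iverson"`.
#' @param w_a,w_l,f_a `c(mean, sd)` pairs (or single numbers) for
#'   `"pace_rathbun"`; moment-matched to beta distributions when uncertainty
#'   is requested. Requires `w_l > w_a`.
#' @param adjustment Multiplicative water bias adjustment for
#'   `"pace_rathbun"`.
#' @param draws Optional tibble of posterior draws (`alpha0`, `alpha1`,
#'   `sigma2`) for the logit model, e.g. from [fit_logit_water_fat()].
#' @return An object of class `pc_water_fat_model`.
#' @export
water_fat_model <- function(kind = c("logit", "iverson", "pace_rathbun"),
                            alpha0 = -1.6, alpha1 = -0.86, sigma2 = 0.09,
                            coef = 1.37,
                            w_a = c(mean = 0.144, sd = 0.015),
                            w_l = c(mean = 0.732, sd = 0.01),
                            f_a = c(mean = 0.90, sd = 0.02),
                            adjustment = 0.967,
                            draws = NULL) {
  kind <- match.arg(kind)
  as_ms <- function(v) {
    if (length(v) == 1L) v <- c(mean = unname(v), sd = 0)
    v[c("mean", "sd")]
  }
  w_a <- as_ms(w_a); w_l <- as_ms(w_l); f_a <- as_ms(f_a)
  if (kind == "pace_rathbun") {
    fr <- c(w_a[["mean"]], w_l[["mean"]], f_a[["mean"]])
    if (any(fr <= 0 | fr >= 1)) {
      rlang::abort("Tissue water/fat fractions must lie in (0, 1).",
                   class = "pinnicomp_config_error")
    }
    if (w_l[["mean"]] <= w_a[["mean"]]) {
      rlang::abort("`w_l` must exceed `w_a` (lean tissue holds more water).",
                   class = "pinnicomp_config_error")
    }
  }
  structure(
    list(kind = kind, alpha0 = alpha0, alpha1 = alpha1, sigma2 = sigma2,
         coef = coef, w_a = w_a, w_l = w_l, f_a = f_a,
         adjustment = adjustment, draws = draws),
    class = "pc_water_fat_model"
  )
}

#' @export
print.pc_water_fat_model <- function(x, ...) {
  cat(sprintf("<water-to-fat model: %s>\n", x$kind))
  switch(x$kind,
    logit = cat(sprintf("  alpha0 %.4g, alpha1 %.4g, sigma2 %.4g%s\n",
                        x$alpha0, x$alpha1, x$sigma2,
                        if (!is.null(x$draws))
                          sprintf(" (+%d posterior draws)", nrow(x$draws))
                        else "")),
    iverson = cat(sprintf("  P_fat = 1 - %.3g * P_H2O\n", x$coef)),
    pace_rathbun = cat(sprintf(
      "  w_a %.3g, w_l %.3g, f_a %.3g, adjustment %.3g\n",
      x$w_a[["mean"]], x$w_l[["mean"]], x$f_a[["mean"]], x$adjustment))
  )
  invisible(x)
}

check_open_unit <- function(p, name = "P_H2O") {
  if (any(p <= 0 | p >= 1)) {
    rlang::abort(paste0("`", name, "` must lie strictly in (0, 1)."),
                 class = "pinnicomp_domain_error")
  }
  invisible(p)
}

#' Proportion fat from proportion water: heteroscedastic logit model
#'
#' Maps the water ratio `x = P_H2O / (1 - P_H2O)` through a linear predictor
#' on the logit scale and inverts. Because the inverse logit is bounded, fat
#' estimates never leave (0, 1), unlike linear rules. With posterior draws
#' on the model, returns the induced distribution per input; the
#' heteroscedastic residual (`sd = x * sigma`) can be added for predictive
#' rather than parameter-only uncertainty.
#'
#' @param p_h2o Proportion water, strictly in (0, 1).
#' @param model A `"logit"` [water_fat_model()].
#' @param posterior If `TRUE` (and the model carries draws), return a tibble
#'   of per-draw fat proportions instead of point values.
#' @param predictive If `TRUE`, add the scaled residual draw (only with
#'   `posterior = TRUE`).
#' @param seed Seed for the residual draws.
#' @return Numeric vector of fat proportions, or a tibble of draws.
#' @export
#' @examples
#' fat_from_water_logit(0.6, water_fat_model("logit"))
fat_from_water_logit <- function(p_h2o, model = water_fat_model("logit"),
                                 posterior = FALSE, predictive = FALSE,
                                 seed = NULL) {
  stopifnot(inherits(model, "pc_water_fat_model"), model$kind == "logit")
  check_open_unit(p_h2o)
  x <- p_h2o / (1 - p_h2o)
  if (!posterior) {
    return(stats::plogis(model$alpha0 + model$alpha1 * x))
  }
  if (is.null(model$draws)) {
    rlang::abort("Model has no posterior draws.", class = "pinnicomp_no_draws")
  }
  d <- model$draws
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(seq_along(p_h2o), function(i) {
    eta <- d$alpha0 + d$alpha1 * x[i]
    if (predictive) {
      eta <- eta + x[i] * stats::rnorm(nrow(d), 0, sqrt(d$sigma2))
    }
    tibble::tibble(p_h2o = p_h2o[i], draw = seq_len(nrow(d)),
                   prop_fat = stats::plogis(eta))
  })
}

#' Proportion fat from proportion water: linear rule
#'
#' The gray-seal linear rule `P_fat = 1 - coef * P_H2O` (coef 1.37). Values
#' can be negative at high water content; they are flagged with a warning
#' but deliberately not clamped, so divergence from the logit model is
#' visible.
#'
#' @param p_h2o Proportion water in \[0, 1\].
#' @param coef Linear coefficient.
#' @return Numeric vector of fat proportions (possibly negative).
#' @export
#' @examples
#' fat_from_water_iverson(0.5)
fat_from_water_iverson <- function(p_h2o, coef = 1.37) {
  if (any(p_h2o < 0 | p_h2o > 1)) {
    rlang::abort("`p_h2o` must lie in [0, 1].",
                 class = "pinnicomp_domain_error")
  }
  out <- 1 - coef * p_h2o
  if (any(out < 0)) {
    rlang::warn(sprintf("%d fat proportion(s) negative under the linear rule.",
                        sum(out < 0)),
                class = "pinnicomp_negative_fat")
  }
  out
}

#' Proportion adipose and fat from proportion water: tissue-water rule
#'
#' Bookkeeping over two tissue pools: adipose tissue with water fraction
#' `w_a` and non-adipose tissue with water fraction `w_l`. After adjusting
#' dilution-derived water for its bias against carcass desiccation
#' (`adjustment`), the adipose proportion interpolates linearly between the
#' all-lean (`P_adj = w_l`) and all-adipose (`P_adj = w_a`) limits; fat is
#' the adipose proportion times the fat fraction of adipose tissue.
#'
#' @param p_h2o Proportion water, strictly in (0, 1).
#' @param model A `"pace_rathbun"` [water_fat_model()].
#' @param n_draws If > 0, draw this many Monte Carlo samples of the
#'   beta-distributed tissue fractions and return a tibble of draws.
#' @param seed Seed for the Monte Carlo draws.
#' @return A tibble with `prop_adipose`, `prop_fat` and `out_of_model`
#'   (point form), or a tibble of draws.
#' @export
#' @examples
#' adipose_and_fat_from_water_pr(0.45, water_fat_model("pace_rathbun"))
adipose_and_fat_from_water_pr <- function(p_h2o,
                                          model = water_fat_model("pace_rathbun"),
                                          n_draws = 0, seed = NULL) {
  stopifnot(inherits(model, "pc_water_fat_model"),
            model$kind == "pace_rathbun")
  check_open_unit(p_h2o)
  p_adj <- model$adjustment * p_h2o
  if (n_draws > 0) {
    if (!is.null(seed)) set.seed(seed)
    wa <- rbeta_ms(n_draws, model$w_a)
    wl <- rbeta_ms(n_draws, model$w_l)
    fa <- rbeta_ms(n_draws, model$f_a)
    return(purrr::map_dfr(seq_along(p_h2o), function(i) {
      adip <- (wl - p_adj[i]) / (wl - wa)
      tibble::tibble(
        p_h2o = p_h2o[i], draw = seq_len(n_draws),
        out_of_model = adip < 0 | adip > 1,
        prop_adipose = pmin(pmax(adip, 0), 1),
        prop_fat = pmin(pmax(adip, 0), 1) * fa
      )
    }))
  }
  wa <- model$w_a[["mean"]]; wl <- model$w_l[["mean"]]
  adip <- (wl - p_adj) / (wl - wa)
  oob <- adip < 0 | adip > 1
  if (any(oob)) {
    rlang::warn(sprintf(
      "%d adjusted water proportion(s) outside (w_a, w_l); adipose clamped.",
      sum(oob)), class = "pinnicomp_out_of_model")
  }
  adip <- pmin(pmax(adip, 0), 1)
  tibble::tibble(
    p_h2o = p_h2o,
    prop_adipose = adip,
    prop_fat = adip * model$f_a[["mean"]],
    out_of_model = oob
  )
}

# Beta draws from a c(mean, sd) spec by moment matching (sd 0 -> constant).
rbeta_ms <- function(n, ms) {
  m <- ms[["mean"]]; s <- ms[["sd"]]
  if (s == 0) return(rep(m, n))
  pars <- beta_moment_match(m, s)
  stats::rbeta(n, pars[["shape1"]], pars[["shape2"]])
}

#' Estimate total body water for a set of animals
#'
#' Combines an injection table, blood count table and standards table into
#' per-animal TBW and proportion water.
#'
#' @param injections Tibble with `animal_id`, `injected_g`, `mass_kg`.
#' @param blood Tibble with `animal_id`, `replicate`, `cpm_ml`, `role`
#'   (`"equilibrium"` or `"background"`).
#' @param standards Standards tibble (see [stock_specific_activity()]).
#' @return Per-animal tibble: `tbw_ml`, `prop_water`, plus the inputs used.
#' @export
estimate_tbw <- function(injections, blood, standards) {
  stock <- stock_specific_activity(standards)
  conc <- blood |>
    dplyr::group_by(.data$animal_id, .data$role) |>
    dplyr::summarise(cpm_ml = mean(.data$cpm_ml), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "role", values_from = "cpm_ml")
  if (!all(c("equilibrium", "background") %in% names(conc))) {
    rlang::abort("Blood table needs both equilibrium and background roles.",
                 class = "pinnicomp_schema_error")
  }
  injections |>
    dplyr::left_join(conc, by = "animal_id") |>
    dplyr::mutate(
      stock_cpm_ml = stock$mean_cpm_ml,
      cpm_inj = .data$injected_g * .data$stock_cpm_ml,
      tbw_ml = tbw(.data$cpm_inj, .data$equilibrium, .data$background),
      prop_water = proportion_water(.data$tbw_ml, .data$mass_kg)
    )
}
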