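# Monte Carlo uncertainty propagation and one-at-a-time sensitivity.

#' Describe an uncertain input
#'
#' One named input to a Monte Carlo propagation: a distribution family with
#' its parameters. Families follow the measurement conventions: `normal` for
#' ordinary measurements, `lognormal` for ultrasound depth readings
#' (strictly positive, multiplicative error), `beta` for proportions, and
#' `fixed` for constants.
#'
#' @param name Input name.
#' @param family `"normal"`, `"lognormal"`, `"beta"`, `"fixed"`, or
#'   `"index"` (uniform over `1..k`; lets an estimator look up rows of a
#'   table of joint posterior draws, with mean-sentinel 0 meaning "use the
#'   point estimates").
#' @param mean,sd Mean and SD on the natural scale (`normal`; for `beta`
#'   they are moment-matched to shape parameters; for `lognormal` they are
#'   the mean/SD of the log readings unless `shape1`/`meanlog` given).
#' @param meanlog,sdlog Log-scale parameters for `lognormal`.
#' @param shape1,shape2 Beta shape parameters (override `mean`/`sd`).
#' @param value Constant for `"fixed"`.
#' @param k Number of indexable draws for `"index"`.
#' @return An object of class `pc_input`.
#' @export
#' @examples
#' input_dist("skin_depth", "normal", mean = 1.32, sd = 0.16)
input_dist <- function(name,
                       family = c("normal", "lognormal", "beta", "fixed",
                                  "index"),
                       mean = NULL, sd = NULL, meanlog = NULL, sdlog = NULL,
                       shape1 = NULL, shape2 = NULL, value = NULL,
                       k = NULL) {
  family <- match.arg(family)
  spec <- switch(family,
    index = {
      # uniform draw over 1..k, used to index a table of joint posterior
      # draws inside an estimator; its "mean" is the sentinel 0, which the
      # estimator interprets as "use the point estimates"
      if (is.null(k) || k < 1) {
        rlang::abort("`index` input needs `k >= 1`.",
                     class = "pinnicomp_config_error")
      }
      list(k = as.integer(k))
    },
    fixed = {
      if (is.null(value)) value <- mean
      if (is.null(value)) {
        rlang::abort("`fixed` input needs `value`.",
                     class = "pinnicomp_config_error")
      }
      list(value = value)
    },
    normal = {
      if (is.null(mean) || is.null(sd) || sd < 0) {
        rlang::abort("`normal` input needs `mean` and `sd >= 0`.",
                     class = "pinnicomp_config_error")
      }
      list(mean = mean, sd = sd)
    },
    lognormal = {
      if (is.null(meanlog) || is.null(sdlog)) {
        if (is.null(mean) || is.null(sd)) {
          rlang::abort("`lognormal` input needs meanlog/sdlog or mean/sd of logs.",
                       class = "pinnicomp_config_error")
        }
        meanlog <- mean; sdlog <- sd
      }
      if (sdlog < 0) {
        rlang::abort("`sdlog` must be >= 0.", class = "pinnicomp_config_error")
      }
      list(meanlog = meanlog, sdlog = sdlog)
    },
    beta = {
      if (is.null(shape1) || is.null(shape2)) {
        if (is.null(mean) || is.null(sd)) {
          rlang::abort("`beta` input needs shape1/shape2 or mean/sd.",
                       class = "pinnicomp_config_error")
        }
        if (sd == 0) {
          # degenerate proportion: keep as a point mass
          return(input_dist(name, "fixed", value = mean))
        }
        mm <- beta_moment_match(mean, sd)
        shape1 <- mm[["shape1"]]; shape2 <- mm[["shape2"]]
      }
      list(shape1 = shape1, shape2 = shape2)
    }
  )
  structure(c(list(name = name, family = family), spec), class = "pc_input")
}

#' @export
print.pc_input <- function(x, ...) {
  pars <- x[setdiff(names(x), c("name", "family"))]
  cat(sprintf("<input %s: %s(%s)>\n", x$name, x$family,
              paste(sprintf("%s = %.4g", names(pars), unlist(pars)),
                    collapse = ", ")))
  invisible(x)
}

#' Moment-match a beta distribution to a mean and SD
#'
#' @param mean,sd Target mean (in (0,1)) and SD.
#' @return Named vector `c(shape1, shape2)`.
#' @export
#' @examples
#' beta_moment_match(0.5, 0.1)  # shape1 = shape2 = 12
beta_moment_match <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) {
    rlang::abort("Beta mean must lie in (0, 1).",
                 class = "pinnicomp_config_error")
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  if (nu <= 0) {
    rlang::abort("SD too large for a beta distribution with this mean.",
                 class = "pinnicomp_config_error")
  }
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

input_mean <- function(inp) {
  switch(inp$family,
    fixed = inp$value,
    normal = inp$mean,
    lognormal = exp(inp$meanlog + inp$sdlog^2 / 2),
    beta = inp$shape1 / (inp$shape1 + inp$shape2),
    index = 0
  )
}

input_draw <- function(inp, n) {
  switch(inp$family,
    fixed = rep(inp$value, n),
    normal = stats::rnorm(n, inp$mean, inp$sd),
    lognormal = stats::rlnorm(n, inp$meanlog, inp$sdlog),
    beta = stats::rbeta(n, inp$shape1, inp$shape2),
    index = as.numeric(sample.int(inp$k, n, replace = TRUE))
  )
}

#' Fit an input distribution to replicate measurements
#'
#' Replicate observer measurements are treated as independent; the input
#' distribution is their sample mean and SD (normal), the mean/SD of the log
#' readings (lognormal, for ultrasound depths), or a moment-matched beta
#' (proportions).
#'
#' @param values Numeric replicate values (>= 2 for a nonzero SD).
#' @param family Distribution family.
#' @param name Input name.
#' @return A [input_dist()] object.
#' @export
#' @examples
#' distribution_from_replicates(c(1, 2, 3), "normal", "girth")
distribution_from_replicates <- function(values,
                                         family = c("normal", "lognormal",
                                                    "beta"),
                                         name = "input") {
  family <- match.arg(family)
  values <- values[is.finite(values)]
  if (length(values) < 1) {
    rlang::abort("Need at least one finite value.",
                 class = "pinnicomp_domain_error")
  }
  s <- if (length(values) > 1) stats::sd(values) else 0
  switch(family,
    normal = input_dist(name, "normal", mean = mean(values), sd = s),
    lognormal = {
      if (any(values <= 0)) {
        rlang::abort("Lognormal fit requires strictly positive readings.",
                     class = "pinnicomp_domain_error")
      }
      lv <- log(values)
      sl <- if (length(lv) > 1) stats::sd(lv) else 0
      input_dist(name, "lognormal", meanlog = mean(lv), sdlog = sl)
    },
    beta = input_dist(name, "beta", mean = mean(values), sd = s)
  )
}

draw_inputs <- function(inputs, n, seed) {
  set.seed(seed)
  cols <- purrr::map(inputs, input_draw, n = n)
  tibble::as_tibble(stats::setNames(cols, purrr::map_chr(inputs, "name")))
}

run_estimator <- function(estimator, draws_tbl) {
  # try a vectorized call over columns first, fall back to row-wise
  n <- nrow(draws_tbl)
  out <- suppressWarnings(tryCatch(do.call(estimator, as.list(draws_tbl)),
                                   error = function(e) NULL))
  if (!is.null(out) && is.numeric(out) && length(out) == n) {
    return(as.numeric(out))
  }
  purrr::pmap_dbl(draws_tbl, function(...) {
    suppressWarnings(
      tryCatch(as.numeric(estimator(...)), error = function(e) NA_real_)
    )
  })
}

#' Propagate input uncertainty through an estimator by Monte Carlo
#'
#' Draws `n` joint samples of all inputs, pushes each through the estimator
#' and summarises the output distribution. Draws on which the estimator
#' fails are excluded and counted; more than 1% failures aborts.
#'
#' @param estimator A function taking the inputs as named arguments (either
#'   vectorized over them or scalar).
#' @param inputs A list of [input_dist()] objects.
#' @param n Number of Monte Carlo draws.
#' @param seed Random seed (propagation is deterministic given
#'   `inputs`, `n`, `seed`).
#' @return A `pc_propagation` object: draws, `mean`, `sd`, 95% interval,
#'   `n`, `seed`, `failure_fraction`.
#' @export
#' @examples
#' pr <- propagate(function(x, y) x + y,
#'                 list(input_dist("x", "normal", mean = 0, sd = 3),
#'                      input_dist("y", "normal", mean = 0, sd = 4)),
#'                 n = 2000, seed = 1)
#' pr$sd  # close to 5
propagate <- function(estimator, inputs, n = 15000, seed = 1) {
  stopifnot(is.function(estimator), length(inputs) > 0)
  draws_tbl <- draw_inputs(inputs, n, seed)
  out <- run_estimator(estimator, draws_tbl)
  fail <- !is.finite(out)
  if (mean(fail) > 0.01) {
    rlang::abort(sprintf(
      "Estimator failed on %.1f%% of draws (limit 1%%).", 100 * mean(fail)),
      class = "pinnicomp_estimator_failure")
  }
  ok <- out[!fail]
  structure(
    list(draws = ok,
         mean = mean(ok),
         sd = if (length(ok) > 1) stats::sd(ok) else 0,
         ci = stats::quantile(ok, c(0.025, 0.975), names = FALSE),
         n = n, seed = seed,
         failure_fraction = mean(fail)),
    class = "pc_propagation"
  )
}

#' @export
print.pc_propagation <- function(x, ...) {
  cat(sprintf(
    "<Monte Carlo propagation: N = %d, mean %.5g, sd %.4g, 95%% [%.5g, %.5g]>\n",
    x$n, x$mean, x$sd, x$ci[1], x$ci[2]))
  if (x$failure_fraction > 0) {
    cat(sprintf("  %.2f%% of draws failed and were excluded\n",
                100 * x$failure_fraction))
  }
  invisible(x)
}

#' One-at-a-time sensitivity analysis
#'
#' Varies each input over its own distribution while holding every other
#' input at its mean, and records the SD of the estimator output. The
#' resulting ranking identifies the measurements whose uncertainty matters
#' most.
#'
#' @inheritParams propagate
#' @return A tibble with one row per input (`input`, `output_sd`,
#'   `output_mean`, `failure_fraction`), sorted by decreasing `output_sd`.
#' @export
sensitivity_oat <- function(estimator, inputs, n = 15000, seed = 1) {
  means <- purrr::map_dbl(inputs, input_mean)
  names(means) <- purrr::map_chr(inputs, "name")
  rows <- purrr::imap(inputs, function(inp, i) {
    set.seed(seed + i)
    tbl <- tibble::as_tibble(as.list(means))[rep(1, n), ]
    tbl[[inp$name]] <- input_draw(inp, n)
    out <- run_estimator(estimator, tbl)
    fail <- !is.finite(out)
    if (mean(fail) > 0.01) {
      rlang::abort(sprintf(
        "Estimator failed on %.1f%% of draws varying `%s`.",
        100 * mean(fail), inp$name),
        class = "pinnicomp_estimator_failure")
    }
    ok <- out[!fail]
    tibble::tibble(
      input = inp$name,
      output_sd = if (length(ok) > 1) stats::sd(ok) else 0,
      output_mean = mean(ok),
      failure_fraction = mean(fail)
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$output_sd))
}
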