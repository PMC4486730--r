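# Metropolis-within-Gibbs fits for the three calibration regressions:
# simple linear, shared-slope with per-site intercepts, and the
# heteroscedastic logit water-to-fat model. All parameters carry uniform
# priors (finite, data-scaled bounds); the inverse error variance carries a
# uniform prior on (0, tau_max]. Proposals are one-parameter-at-a-time
# Gaussian random walks with step sizes adapted during burn-in to an
# acceptance rate near 0.4, then frozen.

mwg_chain <- function(log_lik, init, lower, upper, n_keep, burn, thin,
                      scales) {
  p <- length(init)
  out <- matrix(NA_real_, n_keep, p)
  cur <- init
  ll <- log_lik(cur)
  if (!is.finite(ll)) {
    rlang::abort("Log-likelihood not finite at the initial values.",
                 class = "pinnicomp_sampler_error")
  }
  acc <- rep(0, p)              # adaptation window counter
  acc_tot <- rep(0, p)
  n_raw <- burn + n_keep * thin
  kept <- 0L
  # pre-generated standard-normal steps and log-uniforms: the inner loop
  # does no RNG of its own
  eps <- matrix(stats::rnorm(n_raw * p), n_raw, p)
  logu <- matrix(log(stats::runif(n_raw * p)), n_raw, p)
  window <- 0L
  for (t in seq_len(n_raw)) {
    for (j in seq_len(p)) {
      prop_j <- cur[j] + eps[t, j] * scales[j]
      if (prop_j >= lower[j] && prop_j <= upper[j]) {
        prop <- cur
        prop[j] <- prop_j
        llp <- log_lik(prop)
        if (is.finite(llp) && logu[t, j] < llp - ll) {
          cur <- prop
          ll <- llp
          acc[j] <- acc[j] + 1
          acc_tot[j] <- acc_tot[j] + 1
        }
      }
    }
    window <- window + 1L
    if (t <= burn && window == 50L) {
      rate <- acc / 50
      scales <- scales * exp(pmin(pmax(rate - 0.4, -0.5), 0.5))
      acc[] <- 0
      window <- 0L
    }
    if (t > burn && (t - burn) %% thin == 0) {
      kept <- kept + 1L
      out[kept, ] <- cur
    }
  }
  list(draws = out, acceptance = acc_tot / n_raw, scales = scales)
}

run_mwg <- function(log_lik, inits, lower, upper, par_names,
                    chains, iter, burn, thin, scales, seed) {
  set.seed(seed)
  res <- purrr::map(seq_len(chains), function(ch) {
    init <- inits[[ch]]
    mwg_chain(log_lik, init, lower, upper, iter, burn, thin, scales)
  })
  draws <- purrr::imap_dfr(res, function(r, ch) {
    d <- tibble::as_tibble(stats::setNames(as.data.frame(r$draws), par_names))
    dplyr::bind_cols(tibble::tibble(.chain = ch, .iter = seq_len(nrow(d))), d)
  })
  acc <- do.call(rbind, purrr::map(res, "acceptance"))
  colnames(acc) <- par_names
  list(draws = draws, acceptance = acc)
}

new_pc_fit <- function(model, draws, acceptance, par_names, n_obs, settings,
                       data = NULL) {
  structure(
    list(model = model, draws = draws, acceptance = acceptance,
         par_names = par_names, n_obs = n_obs, settings = settings,
         data = data),
    class = "pc_fit"
  )
}

#' @export
print.pc_fit <- function(x, ...) {
  cat(sprintf("<pc_fit: %s regression, %d obs, %d chains x %d draws>\n",
              x$model, x$n_obs, x$settings$chains, x$settings$iter))
  print(tidy(x), ...)
  invisible(x)
}

# Data-scaled uniform prior half-widths for regression coefficients.
coef_bounds <- function(est, se, scale_fallback, prior_scale) {
  half <- prior_scale * pmax(abs(est), se, scale_fallback, 1e-3)
  list(lower = est - half, upper = est + half)
}

ols_sigma2 <- function(fit) {
  s2 <- sum(stats::resid(fit)^2) / max(stats::df.residual(fit), 1)
  max(s2, 0)
}

# tau (inverse variance) prior: uniform on (0, tau_max], with tau_max far
# above the OLS precision so an (almost) exact fit can push sigma2 toward 0.
tau_upper <- function(s2_ols, y) {
  floor_s2 <- max(s2_ols, 1e-10 * max(stats::var(y), 1e-12))
  1e4 / floor_s2
}

default_settings <- function(chains, iter, burn, thin, seed, prior_scale) {
  list(chains = chains, iter = iter, burn = burn, thin = thin, seed = seed,
       prior_scale = prior_scale)
}

jitter_inits <- function(base, chains, lower, upper, frac = 0.1, seed) {
  # deterministic spread of chain starting points around the OLS solution,
  # kept strictly inside the prior support
  set.seed(seed + 1L)
  floor_ <- lower + 1e-6 * pmax(abs(base), 1e-6)
  purrr::map(seq_len(chains), function(ch) {
    v <- if (ch == 1) {
      base
    } else {
      base + frac * stats::rnorm(length(base)) * pmax(abs(base), 1e-3)
    }
    pmin(pmax(v, floor_), upper)
  })
}

#' Fit a simple linear regression by Metropolis-within-Gibbs
#'
#' Samples the posterior of `y = beta0 + beta1 * x + eps`,
#' `eps ~ N(0, sigma2)`, under uniform priors on the coefficients (centred on
#' the least-squares solution, half-width `prior_scale` times its scale) and
#' a uniform prior on the inverse variance.
#'
#' @param data A data frame.
#' @param x,y Column names (unquoted) of predictor and response.
#' @param chains Number of independent chains (>= 2 recommended).
#' @param iter Kept draws per chain (after thinning).
#' @param burn Burn-in iterations (with step-size adaptation).
#' @param thin Thinning interval.
#' @param prior_scale Half-width multiplier for the coefficient priors.
#' @param seed Random seed.
#' @return A `pc_fit` object; parameters `beta0`, `beta1`, `sigma2`.
#'   Use [tidy()], [glance()], [mcmc_diagnostics()],
#'   [posterior_correlations()].
#' @export
#' @examples
#' d <- make_regression("simple", list(beta0 = 1, beta1 = 2, sigma = 0.5),
#'                      n = 20, seed = 1)
#' fit <- fit_simple(d, x, y, iter = 200, burn = 200, seed = 1)
#' tidy(fit)
fit_simple <- function(data, x, y, chains = 3, iter = 1000, burn = 1000,
                       thin = 5, prior_scale = 100, seed = 1) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  n <- length(xv)
  if (n < 3 || length(yv) != n) {
    rlang::abort("Need x and y of equal length >= 3.",
                 class = "pinnicomp_domain_error")
  }
  if (stats::var(xv) == 0) {
    rlang::abort("Predictor has zero variance; slope not identifiable.",
                 class = "pinnicomp_identifiability_error")
  }
  ols <- stats::lm(yv ~ xv)
  est <- stats::coef(ols)
  se <- sqrt(diag(stats::vcov(ols)))
  se[!is.finite(se)] <- 0
  s2 <- ols_sigma2(ols)
  sy <- stats::sd(yv)
  b <- coef_bounds(est, se, c(sy, sy / max(stats::sd(xv), 1e-12)), prior_scale)
  tau_max <- tau_upper(s2, yv)
  tau0 <- min(1 / max(s2, 1e-12), tau_max)
  lower <- c(b$lower, 0)
  upper <- c(b$upper, tau_max)
  scales <- c(pmax(se, 0.01 * pmax(abs(est), 1e-3)), 0.3 * tau0)

  log_lik <- function(par) {
    tau <- par[3]
    if (tau <= 0) return(-Inf)
    r <- yv - par[1] - par[2] * xv
    0.5 * n * log(tau) - 0.5 * tau * sum(r * r)
  }
  inits <- jitter_inits(c(est, tau0), chains, lower, upper, seed = seed)
  res <- run_mwg(log_lik, inits, lower, upper, c("beta0", "beta1", "tau"),
                 chains, iter, burn, thin, scales, seed)
  res$draws <- res$draws |>
    dplyr::mutate(sigma2 = 1 / .data$tau) |>
    dplyr::select(-"tau")
  new_pc_fit("simple", res$draws, res$acceptance,
             c("beta0", "beta1", "sigma2"), n,
             default_settings(chains, iter, burn, thin, seed, prior_scale),
             data = list(x = xv, y = yv))
}

#' Fit a shared-slope, per-site-intercept regression
#'
#' Samples the posterior of `y = slope * x + intercept[site] + eps`, the
#' instrument-calibration model in which the slope is constant across body
#' sites and each site has its own intercept.
#'
#' @inheritParams fit_simple
#' @param site Column (unquoted) of site labels.
#' @return A `pc_fit`; parameters `slope`, `b_<site>`, `sigma2`.
#' @export
fit_shared_slope <- function(data, x, y, site, chains = 3, iter = 1000,
                             burn = 1000, thin = 5, prior_scale = 100,
                             seed = 1) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  sv <- as.character(rlang::eval_tidy(rlang::enquo(site), data))
  n <- length(xv)
  lev <- unique(sv)
  if (length(lev) < 2) {
    rlang::abort("Need at least two sites.", class = "pinnicomp_domain_error")
  }
  counts <- table(sv)
  if (any(counts < 2)) {
    rlang::warn(paste0("Site(s) with fewer than 2 points: ",
                       paste(names(counts)[counts < 2], collapse = ", ")),
                class = "pinnicomp_sparse_site")
  }
  fsite <- factor(sv, levels = lev)
  X <- stats::model.matrix(~ 0 + fsite)
  ols <- tryCatch(stats::lm(yv ~ 0 + xv + X),
                  error = function(e) NULL)
  est <- stats::coef(ols)
  if (is.null(ols) || anyNA(est)) {
    rlang::abort("Singular design; shared-slope model not identifiable.",
                 class = "pinnicomp_identifiability_error")
  }
  se <- sqrt(diag(stats::vcov(ols)))
  se[!is.finite(se)] <- 0
  s2 <- ols_sigma2(ols)
  sy <- stats::sd(yv)
  b <- coef_bounds(est, se, sy, prior_scale)
  tau_max <- tau_upper(s2, yv)
  tau0 <- min(1 / max(s2, 1e-12), tau_max)
  lower <- c(b$lower, 0)
  upper <- c(b$upper, tau_max)
  scales <- c(pmax(se, 0.01 * pmax(abs(est), 1e-3)), 0.3 * tau0)
  site_idx <- as.integer(fsite)
  p_int <- length(lev)

  log_lik <- function(par) {
    tau <- par[p_int + 2]
    if (tau <= 0) return(-Inf)
    r <- yv - par[1] * xv - par[1 + site_idx]
    0.5 * n * log(tau) - 0.5 * tau * sum(r * r)
  }
  par_names <- c("slope", paste0("b_", lev), "tau")
  inits <- jitter_inits(c(est, tau0), chains, lower, upper, seed = seed)
  res <- run_mwg(log_lik, inits, lower, upper, par_names,
                 chains, iter, burn, thin, scales, seed)
  res$draws <- res$draws |>
    dplyr::mutate(sigma2 = 1 / .data$tau) |>
    dplyr::select(-"tau")
  new_pc_fit("shared_slope", res$draws, res$acceptance,
             c("slope", paste0("b_", lev), "sigma2"), n,
             default_settings(chains, iter, burn, thin, seed, prior_scale),
             data = list(x = xv, y = yv, site = sv))
}

#' Fit the heteroscedastic logit water-to-fat model
#'
#' Samples the posterior of
#' `logit(P_fat) = alpha0 + alpha1 * x + x * eps`, where
#' `x = P_H2O / (1 - P_H2O)` is the water ratio and `eps ~ N(0, sigma2)`:
#' residual spread grows proportionally with the water ratio.
#'
#' @inheritParams fit_simple
#' @param p_h2o,p_fat Columns (unquoted) of proportion water and proportion
#'   fat, both strictly inside (0, 1).
#' @return A `pc_fit`; parameters `alpha0`, `alpha1`, `sigma2`. Pass the
#'   result to [as_water_fat_model()] to use it for conversion.
#' @export
fit_logit_water_fat <- function(data, p_h2o, p_fat, chains = 3, iter = 1000,
                                burn = 1000, thin = 5, prior_scale = 100,
                                seed = 1) {
  pw <- rlang::eval_tidy(rlang::enquo(p_h2o), data)
  pf <- rlang::eval_tidy(rlang::enquo(p_fat), data)
  check_open_unit(pw, "p_h2o")
  check_open_unit(pf, "p_fat")
  n <- length(pw)
  if (n < 3) {
    rlang::abort("Need at least 3 observations.",
                 class = "pinnicomp_domain_error")
  }
  xr <- pw / (1 - pw)
  yl <- stats::qlogis(pf)
  w <- 1 / xr^2
  ols <- stats::lm(yl ~ xr, weights = w)
  est <- stats::coef(ols)
  se <- sqrt(diag(stats::vcov(ols)))
  se[!is.finite(se)] <- 0
  # scaled residual variance (per unit water ratio)
  s2 <- sum(w * stats::resid(ols)^2) / max(n - 2, 1)
  sy <- stats::sd(yl)
  b <- coef_bounds(est, se, c(sy, sy / max(stats::sd(xr), 1e-12)), prior_scale)
  tau_max <- tau_upper(s2, yl / xr)
  tau0 <- min(1 / max(s2, 1e-12), tau_max)
  lower <- c(b$lower, 0)
  upper <- c(b$upper, tau_max)
  scales <- c(pmax(se, 0.01 * pmax(abs(est), 1e-3)), 0.3 * tau0)

  log_lik <- function(par) {
    tau <- par[3]
    if (tau <= 0) return(-Inf)
    z <- (yl - par[1] - par[2] * xr) / xr
    0.5 * n * log(tau) - 0.5 * tau * sum(z * z)
  }
  inits <- jitter_inits(c(est, tau0), chains, lower, upper, seed = seed)
  res <- run_mwg(log_lik, inits, lower, upper, c("alpha0", "alpha1", "tau"),
                 chains, iter, burn, thin, scales, seed)
  res$draws <- res$draws |>
    dplyr::mutate(sigma2 = 1 / .data$tau) |>
    dplyr::select(-"tau")
  new_pc_fit("logit_heteroscedastic", res$draws, res$acceptance,
             c("alpha0", "alpha1", "sigma2"), n,
             default_settings(chains, iter, burn, thin, seed, prior_scale),
             data = list(p_h2o = pw, p_fat = pf))
}

#' Turn a fitted logit water-to-fat regression into a conversion model
#'
#' @param fit A `pc_fit` from [fit_logit_water_fat()].
#' @return A `"logit"` [water_fat_model()] whose point parameters are the
#'   posterior means and which carries the joint posterior draws.
#' @export
as_water_fat_model <- function(fit) {
  stopifnot(inherits(fit, "pc_fit"), fit$model == "logit_heteroscedastic")
  d <- fit$draws
  water_fat_model(
    "logit",
    alpha0 = mean(d$alpha0), alpha1 = mean(d$alpha1),
    sigma2 = mean(d$sigma2),
    draws = dplyr::select(d, "alpha0", "alpha1", "sigma2")
  )
}

draw_matrix <- function(fit) {
  as.matrix(fit$draws[, fit$par_names, drop = FALSE])
}

#' @rdname fit_simple
#' @param x A `pc_fit` object.
#' @param conf.level Width of the posterior interval.
#' @param ... Unused.
#' @export
tidy.pc_fit <- function(x, conf.level = 0.95, ...) {
  a <- (1 - conf.level) / 2
  m <- draw_matrix(x)
  tibble::tibble(
    term = colnames(m),
    estimate = unname(colMeans(m)),
    std.error = unname(apply(m, 2, stats::sd)),
    conf.low = unname(apply(m, 2, stats::quantile, probs = a)),
    conf.high = unname(apply(m, 2, stats::quantile, probs = 1 - a))
  )
}

#' @rdname fit_simple
#' @export
glance.pc_fit <- function(x, ...) {
  diag <- mcmc_diagnostics(x)
  tibble::tibble(
    model = x$model,
    n_obs = x$n_obs,
    n_chains = x$settings$chains,
    n_draws = nrow(x$draws),
    mean_acceptance = mean(x$acceptance),
    max_lag1 = max(diag$lag1$lag1, na.rm = TRUE),
    max_chain_discrepancy = max(diag$between$discrepancy_sd, 0, na.rm = TRUE),
    converged = diag$pass
  )
}

#' Pairwise posterior parameter correlations
#'
#' @param fit A `pc_fit` object.
#' @return A correlation matrix over the model parameters.
#' @export
posterior_correlations <- function(fit) {
  stats::cor(draw_matrix(fit))
}

#' Convergence diagnostics for posterior samples
#'
#' Reports lag-1 autocorrelation per parameter per chain and the largest
#' between-chain mean discrepancy in pooled posterior-SD units, with
#' pass/fail against thresholds. Mixing practice for these samplers is
#' multiple independent chains with low lag-1 autocorrelation.
#'
#' @param x A `pc_fit`, or a tibble of draws with a `.chain` column and one
#'   column per parameter.
#' @param lag1_threshold Maximum acceptable lag-1 autocorrelation.
#' @param discrepancy_threshold Maximum acceptable between-chain mean
#'   difference, in units of the pooled posterior SD.
#' @return A list with elements `lag1` (tibble), `between` (tibble),
#'   `pass` (logical).
#' @export
mcmc_diagnostics <- function(x, lag1_threshold = 0.5,
                             discrepancy_threshold = 0.2) {
  draws <- if (inherits(x, "pc_fit")) {
    dplyr::select(x$draws, ".chain", dplyr::all_of(x$par_names))
  } else {
    x
  }
  if (!".chain" %in% names(draws)) {
    rlang::abort("Draws need a `.chain` column.",
                 class = "pinnicomp_schema_error")
  }
  pars <- setdiff(names(draws), c(".chain", ".iter"))
  chains <- sort(unique(draws$.chain))
  if (length(chains) < 2) {
    rlang::warn("Single chain: between-chain diagnostics unavailable.",
                class = "pinnicomp_single_chain")
  }
  lag1 <- tidyr::expand_grid(chain = chains, parameter = pars) |>
    dplyr::mutate(lag1 = purrr::map2_dbl(.data$chain, .data$parameter,
      function(ch, pp) {
        v <- draws[[pp]][draws$.chain == ch]
        # a constant chain is stuck, i.e. maximally autocorrelated
        if (stats::sd(v) == 0) return(1)
        stats::cor(v[-length(v)], v[-1])
      }))
  between <- purrr::map_dfr(pars, function(pp) {
    v <- draws[[pp]]
    s <- stats::sd(v)
    if (length(chains) < 2 || s == 0) {
      return(tibble::tibble(parameter = pp, discrepancy_sd = NA_real_))
    }
    mns <- tapply(v, draws$.chain, mean)
    tibble::tibble(parameter = pp,
                   discrepancy_sd = (max(mns) - min(mns)) / s)
  })
  pass <- all(lag1$lag1 <= lag1_threshold, na.rm = TRUE) &&
    all(between$discrepancy_sd <= discrepancy_threshold, na.rm = TRUE)
  list(lag1 = lag1, between = between, pass = pass,
       thresholds = c(lag1 = lag1_threshold,
                      discrepancy = discrepancy_threshold))
}
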