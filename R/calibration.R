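# Simulation-based calibration of the samplers: do 95% posterior intervals
# cover the generating parameters at the nominal rate?

#' Interval-coverage study for a regression sampler
#'
#' Generates `n_rep` synthetic datasets with [make_regression()], fits each
#' with the matching Metropolis-within-Gibbs sampler, and counts how often
#' the central 95% posterior interval contains the generating value of each
#' parameter.
#'
#' @param kind `"simple"`, `"shared_slope"` or `"logit"`.
#' @param params Generating parameters (see [make_regression()]).
#' @param n Observations per dataset (per site for `shared_slope`).
#' @param n_rep Number of replicate datasets.
#' @param seed Base seed; dataset `i` uses `seed + i`.
#' @param chains,iter,burn,thin Sampler settings per fit.
#' @param conf.level Interval mass checked.
#' @return A tibble with one row per parameter: `term`, `truth`, `covered`
#'   (count), `n_rep`, `coverage` (proportion).
#' @export
#' @examples
#' coverage_study("simple", list(beta0 = 1, beta1 = 2, sigma = 1),
#'                n = 12, n_rep = 5, iter = 150, burn = 150)
coverage_study <- function(kind = c("simple", "shared_slope", "logit"),
                           params = list(), n = 14, n_rep = 100, seed = 1,
                           chains = 2, iter = 600, burn = 400, thin = 3,
                           conf.level = 0.95) {
  kind <- match.arg(kind)
  truth <- switch(kind,
    simple = {
      p <- modifyList(list(beta0 = 0, beta1 = 1, sigma = 1), params)
      c(beta0 = p$beta0, beta1 = p$beta1)
    },
    shared_slope = {
      p <- modifyList(list(slope = 1,
                           intercepts = c(pelvis = 1, umbilicus = 2),
                           sigma = 1), params)
      c(slope = p$slope,
        stats::setNames(p$intercepts, paste0("b_", names(p$intercepts))))
    },
    logit = {
      p <- modifyList(list(alpha0 = -1.6, alpha1 = -0.86, sigma = 0.3),
                      params)
      c(alpha0 = p$alpha0, alpha1 = p$alpha1)
    }
  )
  hits <- stats::setNames(rep(0L, length(truth)), names(truth))
  for (i in seq_len(n_rep)) {
    d <- make_regression(kind, params, n = n, seed = seed + i)
    fit <- switch(kind,
      simple = fit_simple(d, .data$x, .data$y, chains = chains, iter = iter,
                          burn = burn, thin = thin, seed = seed + i),
      shared_slope = fit_shared_slope(d, .data$x, .data$y, .data$site,
                                      chains = chains, iter = iter,
                                      burn = burn, thin = thin,
                                      seed = seed + i),
      logit = fit_logit_water_fat(d, .data$p_h2o, .data$p_fat,
                                  chains = chains, iter = iter, burn = burn,
                                  thin = thin, seed = seed + i)
    )
    td <- tidy(fit, conf.level = conf.level)
    for (nm in names(truth)) {
      row <- td[td$term == nm, ]
      if (nrow(row) == 1 &&
          row$conf.low <= truth[[nm]] && truth[[nm]] <= row$conf.high) {
        hits[nm] <- hits[nm] + 1L
      }
    }
  }
  tibble::tibble(term = names(truth), truth = unname(truth),
                 covered = unname(hits), n_rep = n_rep,
                 coverage = unname(hits) / n_rep)
}
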