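# ggplot2 visualisations for fitted objects and uncertainty results.

#' Plot posterior marginal distributions of a fitted regression
#'
#' @param object A `pc_fit`.
#' @param ... Unused.
#' @return A ggplot: one density panel per parameter, coloured by chain.
#' @export
autoplot.pc_fit <- function(object, ...) {
  long <- object$draws |>
    tidyr::pivot_longer(dplyr::all_of(object$par_names),
                        names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$value,
                                     colour = factor(.data$.chain))) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density", colour = "chain",
                  title = paste0(object$model, " regression posterior")) +
    ggplot2::theme_minimal()
}

#' Plot a Monte Carlo propagation result
#'
#' @param object A `pc_propagation` from [propagate()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot histogram of the output draws with mean and 95% bounds.
#' @export
autoplot.pc_propagation <- function(object, bins = 60, ...) {
  df <- tibble::tibble(value = object$draws)
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$mean, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$ci, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::labs(x = "estimator output", y = "draws",
                  title = sprintf("Monte Carlo propagation (N = %d)",
                                  object$n)) +
    ggplot2::theme_minimal()
}

#' Plot a one-at-a-time sensitivity ranking
#'
#' @param sens A tibble from [sensitivity_oat()] (or one animal's
#'   `sensitivity` entry from [cones_uncertainty()]).
#' @param top Show only the `top` most influential inputs (default all).
#' @return A ggplot bar chart of per-input output SDs, largest first.
#' @export
plot_sensitivity <- function(sens, top = Inf) {
  df <- utils::head(dplyr::arrange(sens, dplyr::desc(.data$output_sd)),
                    if (is.finite(top)) top else nrow(sens))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$input, .data$output_sd),
    y = .data$output_sd)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "SD of output when only this input varies",
                  title = "One-at-a-time sensitivity") +
    ggplot2::theme_minimal()
}

#' Compare the water-to-fat conversion models over a range of water values
#'
#' Shows where the bounded logit conversion and the linear rule diverge at
#' high proportion water (where the linear rule goes negative).
#'
#' @param logit_model A `"logit"` [water_fat_model()].
#' @param p_range Range of proportion water values.
#' @return A ggplot of proportion fat vs proportion water for the logit,
#'   linear and tissue-water conversions.
#' @export
plot_water_fat_models <- function(logit_model = water_fat_model("logit"),
                                  p_range = c(0.4, 0.85)) {
  pw <- seq(p_range[1], p_range[2], length.out = 200)
  pr <- suppressWarnings(
    adipose_and_fat_from_water_pr(pw, water_fat_model("pace_rathbun")))
  df <- dplyr::bind_rows(
    tibble::tibble(p_h2o = pw, model = "logit",
                   prop_fat = fat_from_water_logit(pw, logit_model)),
    tibble::tibble(p_h2o = pw, model = "linear (1.37)",
                   prop_fat = suppressWarnings(fat_from_water_iverson(pw))),
    tibble::tibble(p_h2o = pw, model = "tissue water", prop_fat = pr$prop_fat)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$p_h2o, .data$prop_fat,
                                   colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "proportion total body water", y = "proportion fat",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
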