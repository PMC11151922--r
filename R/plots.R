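# ggplot2 views of the result objects.

level_order <- c("population", "community", "region")

#' Plot invariability across organizational levels
#'
#' One point per variable and level (population, community, region), on a
#' log10 y axis, mirroring the classic scatter of invariability against
#' organizational level. Infinite invariabilities (zero CV) are dropped
#' with a warning from ggplot2.
#'
#' @param object A `study_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.study_result <- function(object, ...) {
  dat <- level_ordering_check(object) |>
    tidyr::pivot_longer(dplyr::starts_with("inv_"),
                        names_to = "level", names_prefix = "inv_",
                        values_to = "invariability") |>
    mutate(level = factor(.data$level, levels = level_order))
  ggplot(dat, aes(x = .data$level, y = .data$invariability,
                  colour = .data$variable, group = .data$variable)) +
    geom_line(alpha = 0.6) +
    geom_point(size = 2.5) +
    scale_y_log10() +
    labs(x = "organizational level", y = "temporal invariability (1/CV)",
         colour = "variable") +
    theme_minimal()
}

#' Plot species and spatial synchrony per variable
#'
#' @param result A `study_result`.
#' @return A ggplot with one point per variable for local species synchrony
#'   and spatial synchrony (both in `[0, 1]`; values below 1 indicate
#'   stabilizing, compensatory dynamics).
#' @export
plot_synchrony <- function(result) {
  stopifnot(inherits(result, "study_result"))
  dat <- tidy(result) |>
    filter(.data$component %in% c("phi_s2c_l", "phi_c_l2r")) |>
    mutate(index = ifelse(.data$component == "phi_s2c_l",
                          "species synchrony (local)", "spatial synchrony"))
  ggplot(dat, aes(x = .data$index, y = .data$value, colour = .data$variable)) +
    geom_point(size = 2.5, position = position_dodge(width = 0.3)) +
    ylim(0, 1) +
    labs(x = NULL, y = expression(psi), colour = "variable") +
    theme_minimal()
}

#' Plot a Taylor power-law fit
#'
#' Log-log scatter of the (mean, sd) pairs with the fitted line; the slope
#' is the scaling exponent `b`.
#'
#' @param object A `taylor_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.taylor_fit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$mean, y = .data$sd)) +
    geom_point(alpha = 0.7) +
    geom_abline(slope = if (object$convention == "sd_vs_mean")
                  object$b else object$b / 2,
                intercept = if (object$convention == "sd_vs_mean")
                  object$intercept else object$intercept / 2) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "temporal mean", y = "temporal SD",
         title = sprintf("b = %.3f (R² = %.3f, n = %d)",
                         object$b, object$r_squared, object$n_units)) +
    theme_minimal()
}
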