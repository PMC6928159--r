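#' Tidy a fitted recovery boundary
#'
#' @param x a `recovery_boundary`.
#' @param ... unused.
#' @return tibble with one row per boundary term (`slope`, `intercept`),
#'   with bootstrap standard errors when attached.
#' @export
tidy.recovery_boundary <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept),
         std.error = c(x$slope_sd %||% NA_real_, x$intercept_sd %||% NA_real_))
}

#' @rdname tidy.recovery_boundary
#' @export
glance.recovery_boundary <- function(x, ...) {
  tibble(n = x$n, cost = x$cost, training_accuracy = x$training_accuracy,
         margin = x$margin, n_boot = x$n_boot %||% NA_integer_)
}

#' Tidy a trained recovery model
#'
#' @param x a `recovery_model` from [train_recovery_model()].
#' @param ... unused.
#' @return tibble with rows slope, intercept and fa_threshold.
#' @export
tidy.recovery_model <- function(x, ...) {
  dplyr::bind_rows(
    tidy(x$boundary),
    tibble(term = "fa_threshold", estimate = x$fa$threshold,
           std.error = x$fa$sd))
}

#' @rdname tidy.recovery_model
#' @export
glance.recovery_model <- function(x, ...) {
  tibble(n_training = x$n_training, n_excluded = x$n_excluded,
         training_accuracy = x$boundary$training_accuracy,
         slope = x$boundary$slope, intercept = x$boundary$intercept,
         fa_threshold = x$fa$threshold,
         platt_A = x$platt$A, platt_B = x$platt$B)
}

#' @rdname fit_platt
#' @param x a `platt_model`.
#' @export
tidy.platt_model <- function(x, ...) {
  tibble(term = c("A", "B"), estimate = c(x$A, x$B))
}

#' Plot a recovery boundary over its training points
#'
#' Scatter of the training (AD, RD) records colored by label, with the
#' fitted decision line.
#'
#' @param object a `recovery_boundary`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.recovery_boundary <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$ad, y = .data$rd,
                               color = .data$recovered)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linewidth = 0.8) +
    ggplot2::scale_color_manual(
      values = c(`TRUE` = "#1b9e77", `FALSE` = "#d95f02"),
      labels = c(`TRUE` = "recovered", `FALSE` = "non-recovered"),
      name = NULL) +
    ggplot2::labs(x = expression(AD ~ (mu * m^2 / ms)),
                  y = expression(RD ~ (mu * m^2 / ms)))
}

#' Plot the distal RD-vs-AD plane of a simulated study
#'
#' One panel per timepoint, mirroring the slice-wise scatter view of the
#' study: each point is a distal slice record, colored by cohort.
#'
#' @param object a `nerve_study` from [simulate_study()].
#' @param region region to display (default `"distal"`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.nerve_study <- function(object, region = "distal", ...) {
  d <- dplyr::filter(object$slices, .data$region == !!region)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ad, y = .data$rd,
                                  color = .data$cohort)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::facet_wrap(~week, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(AD ~ (mu * m^2 / ms)),
                  y = expression(RD ~ (mu * m^2 / ms)), color = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
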