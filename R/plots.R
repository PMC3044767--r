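#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line labs
#'   scale_x_log10 facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot an H-ratio fit over its data
#' @param object An [fit_hratio()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hratio_fit <- function(object, ...) {
  grid <- tibble(contrast = exp(seq(log(min(object$data$contrast)),
                                    log(100), length.out = 200)))
  grid$response <- predict(object, grid$contrast)
  ggplot(object$data, aes(x = .data$contrast, y = .data$response)) +
    geom_point() +
    geom_line(data = grid, colour = "steelblue") +
    scale_x_log10() +
    labs(x = "contrast (%)", y = "response",
         title = sprintf("H-ratio fit: R_max = %.3g, C50 = %.3g%%, n = %.2f",
                         object$R_max, object$C50, object$n_exp))
}

#' Plot a threshold power-law fit over its data
#' @param object A [fit_powerlaw()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  grid <- tibble(I = seq(min(object$data$I), max(object$data$I),
                         length.out = 200))
  grid$y <- predict(object, grid$I)
  ggplot(object$data, aes(x = .data$I, y = .data$y)) +
    geom_point() +
    geom_line(data = grid, colour = "steelblue") +
    labs(x = "input", y = "response",
         title = sprintf("Power-law fit: beta = %.2f, threshold = %.3g",
                         object$beta, object$threshold))
}

#' Plot network tuning curves by contrast
#' @param object A [network_experiment()] result.
#' @param response Column to plot (`"rate"` or `"V_clip"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.network_responses <- function(object, response = "rate", ...) {
  ggplot(as_tibble(object),
         aes(x = .data$theta, y = .data[[response]],
             colour = factor(.data$contrast))) +
    geom_line() +
    facet_wrap(~pop, scales = "free_y") +
    labs(x = "preferred orientation (deg)", y = response,
         colour = "contrast (%)")
}

#' Plot the excitatory rate-vs-input diagnostic curve of a CRF-shape
#' classification
#' @param object A [classify_crf_shape()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crf_shape <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$I0, y = .data$nu_E0)) +
    geom_line() +
    geom_point(size = 0.8) +
    scale_x_log10() +
    labs(x = "LGN input I0", y = "excitatory peak rate",
         title = sprintf("CRF shape: %s (criterion margin %.3g)",
                         object$class, object$margin))
}
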