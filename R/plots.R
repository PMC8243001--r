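# ggplot2 displays for the main result types. Kept deliberately plain:
# faceted raw views that mirror the figures practitioners draw for these
# experiments.

#' Plot a synthetic clamp experiment
#'
#' Photocurrent traces facetted by holding potential, coloured by irradiance.
#'
#' @param object a `clamp_experiment` from [generate_clamp_traces()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.clamp_experiment <- function(object, ...) {
  ggplot2::ggplot(object$traces,
                  ggplot2::aes(x = .data$time, y = .data$current,
                               colour = factor(signif(.data$irradiance, 3)),
                               group = .data$irradiance)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~voltage, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = "current",
                  colour = expression(irradiance ~ (W / m^2))) +
    ggplot2::theme_minimal()
}

#' Plot model-vs-target features of a fit
#'
#' One panel per feature, model value against target value across the
#' stimulation grid; the identity line marks a perfect fit.
#'
#' @param object an `opsin_fit` from [fit_opsin()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.opsin_fit <- function(object, ...) {
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(x = .data$target, y = .data$model,
                               colour = .data$voltage)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = "target", y = "model") +
    ggplot2::theme_minimal()
}

#' Plot a strength-duration analysis
#'
#' Threshold temporal-average current (with the Hill-Lapicque fit) and
#' threshold irradiance (with the mapped composite curve) against pulse
#' duration, on log-log axes.
#'
#' @param object an `sdc_result` from [build_sdc()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.sdc_result <- function(object, ...) {
  th <- object$thresholds
  hl <- object$hill_lapicque
  mp <- object$mapping
  pd_fine <- 10^seq(log10(min(th$pd)), log10(max(th$pd)), length.out = 200)
  tac_fine <- hl$rheobase / (1 - exp(-pd_fine * log(2) / hl$chronaxie))
  curves <- dplyr::bind_rows(
    tibble::tibble(pd = pd_fine, value = tac_fine,
                   panel = "TAC (uA/cm^2)"),
    tibble::tibble(pd = pd_fine, value = mp$a * tac_fine^mp$b + mp$c,
                   panel = "irradiance (W/m^2)"))
  points <- dplyr::bind_rows(
    tibble::tibble(pd = th$pd, value = th$tac, panel = "TAC (uA/cm^2)"),
    tibble::tibble(pd = th$pd, value = th$irradiance,
                   panel = "irradiance (W/m^2)"))
  ggplot2::ggplot(points, ggplot2::aes(x = .data$pd, y = .data$value)) +
    ggplot2::geom_line(data = curves, linetype = 2, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "pulse duration (s)", y = "threshold") +
    ggplot2::theme_minimal()
}

#' Plot a membrane-potential trace
#'
#' @param trace output of [simulate_rs_neuron()].
#' @param spikes optional spike times to mark.
#' @return A ggplot.
#' @export
plot_membrane <- function(trace, spikes = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time, y = .data$v)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "membrane potential (mV)") +
    ggplot2::theme_minimal()
  if (!is.null(spikes) && length(spikes)) {
    p <- p + ggplot2::geom_vline(xintercept = spikes, colour = "red",
                                 alpha = 0.3, linewidth = 0.2)
  }
  p
}
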