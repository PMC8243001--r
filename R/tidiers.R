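#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an opsin parameter set
#'
#' @param x an [opsin_params()].
#' @param ... unused.
#' @return A tibble with one row per parameter (`block`, `idx`, `value`).
#' @export
tidy.opsin_params <- function(x, ...) {
  blocks <- c("tauO_I", "tauO_V", "tauR_I", "tauR_V", "Oinf", "Rinf")
  rows <- purrr::map_dfr(blocks, function(b) {
    tibble::tibble(block = b, idx = seq_along(x[[b]]), value = x[[b]])
  })
  extra <- tibble::tibble(block = c("g", "E"), idx = 1L, value = c(x$g, x$E))
  if (!is.null(x$Grect)) {
    extra <- dplyr::bind_rows(
      extra, tibble::tibble(block = "Grect", idx = 1:3, value = x$Grect))
  }
  dplyr::bind_rows(rows, extra)
}

#' Tidy / summarize a fitted opsin model
#'
#' `tidy()` returns the intermediate and final parameter values side by side;
#' `glance()` returns the one-row cost summary.
#'
#' @param x an `opsin_fit` from [fit_opsin()].
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.opsin_fit <- function(x, ...) {
  dplyr::full_join(
    dplyr::rename(tidy.opsin_params(x$intermediate), intermediate = "value"),
    dplyr::rename(tidy.opsin_params(x$final), final = "value"),
    by = c("block", "idx"))
}

#' @rdname tidy.opsin_fit
#' @export
glance.opsin_fit <- function(x, ...) {
  tibble::tibble(
    n_conditions = nrow(dplyr::distinct(x$features, .data$irradiance,
                                        .data$voltage)),
    cost_intermediate = x$cost_intermediate,
    cost_intermediate_ext = x$cost_intermediate_ext,
    cost_final = x$cost_final,
    worst_rel_error = max(abs(x$residuals$rel_error), na.rm = TRUE),
    budget_exhausted = x$budget_exhausted)
}

#' Tidy / summarize a strength-duration analysis
#'
#' `tidy()` returns the per-duration thresholds; `glance()` the fitted
#' rheobases, chronaxies, mapping coefficients and goodness-of-fit values.
#'
#' @param x an `sdc_result` from [build_sdc()].
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.sdc_result <- function(x, ...) x$thresholds

#' @rdname tidy.sdc_result
#' @export
glance.sdc_result <- function(x, ...) {
  tibble::tibble(
    tac_rheobase = x$hill_lapicque$rheobase,
    tac_chronaxie_ms = 1000 * x$hill_lapicque$chronaxie,
    adj_r2_tac_pd = x$hill_lapicque$adj_r2,
    map_a = x$mapping$a, map_b = x$mapping$b, map_c = x$mapping$c,
    adj_r2_mapping = x$mapping$adj_r2,
    irr_rheobase = x$irradiance_domain$rheobase,
    irr_chronaxie_ms = 1000 * x$irradiance_domain$chronaxie,
    adj_r2_irradiance_pd = x$adj_r2_irradiance_pd)
}

#' Tidy a mono-exponential fit
#'
#' @param x a `monoexp_fit` from [fit_monoexp()].
#' @param ... unused.
#' @return A one-row tibble with `A`, `tau`, `C`, `rss`.
#' @export
tidy.monoexp_fit <- function(x, ...) {
  tibble::tibble(A = x$A, tau = x$tau, C = x$C, rss = x$rss)
}
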