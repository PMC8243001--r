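#' Synthetic voltage-clamp experiment configuration
#'
#' Describes the emulated experimental design: a grid of irradiances and
#' holding potentials probed with single rectangular pulses, plus two-pulse
#' recovery series at a subset of conditions, generated from a known
#' parameter set with additive white Gaussian noise.
#'
#' Defaults mirror a typical channelrhodopsin voltage-clamp study: five
#' log-spaced irradiances over 1e2..1e4 W/m^2, holding potentials -80..+40 mV
#' in 20 mV steps, 0.5 s pulses sampled at 0.15 ms, recovery series at the
#' three highest irradiances at -60 mV, and noise at 1% of the grid-maximal
#' peak.
#'
#' @param params generating [opsin_params()] (default: the final
#'   reciprocal-sum channelrhodopsin-2(H134R) fixture).
#' @param irradiances irradiance grid (W/m^2).
#' @param voltages voltage grid (mV).
#' @param pulse_s single-pulse duration (s).
#' @param t_on pulse onset (s); the pre-onset window provides the baseline.
#' @param post_s recorded time after the pulse (s).
#' @param dt single-pulse sample interval (s).
#' @param dt_two two-pulse sample interval (s).
#' @param recovery_irradiances irradiances of the two-pulse series (W/m^2).
#' @param recovery_voltage holding potential of the two-pulse series (mV).
#' @param intervals two-pulse dark gaps (s), strictly increasing.
#' @param noise_sd_rel Gaussian noise standard deviation, relative to the
#'   largest peak magnitude on the grid.
#' @param seed RNG seed for the noise.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(params = opsin_fixture("rsrs_final"),
                         irradiances = 10^seq(2, 4, length.out = 5),
                         voltages = seq(-80, 40, by = 20),
                         pulse_s = 0.5, t_on = 0.05, post_s = 0.3,
                         dt = 1.5e-4, dt_two = 1e-3,
                         recovery_irradiances = 10^c(3, 3.5, 4),
                         recovery_voltage = -60,
                         intervals = c(0.3, 0.75, 1.5, 2.5, 4, 6, 9, 13, 18),
                         noise_sd_rel = 0.01, seed = 1L) {
  params <- validate_opsin_params(params)
  stopifnot(length(irradiances) > 0, length(voltages) > 0,
            noise_sd_rel >= 0, pulse_s > 0, dt > 0, dt_two > 0)
  structure(list(params = params, irradiances = irradiances,
                 voltages = voltages, pulse_s = pulse_s, t_on = t_on,
                 post_s = post_s, dt = dt, dt_two = dt_two,
                 recovery_irradiances = recovery_irradiances,
                 recovery_voltage = recovery_voltage, intervals = intervals,
                 noise_sd_rel = noise_sd_rel, seed = as.integer(seed)),
            class = "synth_config")
}

.protocol_of <- function(config, irradiance, voltage) {
  clamp_protocol(irradiance, voltage, t_on = config$t_on,
                 t_off = config$t_on + config$pulse_s,
                 t_end = config$t_on + config$pulse_s + config$post_s)
}

#' Generate a synthetic voltage-clamp experiment
#'
#' Simulates the closed-form photocurrent at every grid condition, the
#' two-pulse recovery series at the configured conditions, adds seeded white
#' Gaussian noise, and records the generating model's ground-truth features
#' (measured by the same extraction operations on the noiseless traces).
#'
#' @param config a [synth_config()].
#' @return An object of class `clamp_experiment`: list with
#'   `traces` (long tibble: `irradiance`, `voltage`, `time`, `current`),
#'   `two_pulse` (tibble: `irradiance`, `voltage`, `interval`, `ratio`),
#'   `truth` (ground-truth feature tibble), and `config`.
#' @export
generate_clamp_traces <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  grid <- tidyr::expand_grid(irradiance = config$irradiances,
                             voltage = config$voltages)
  clean <- purrr::pmap(grid, function(irradiance, voltage) {
    pr <- .protocol_of(config, irradiance, voltage)
    tr <- photocurrent(config$params, pr, dt = config$dt)
    tibble::tibble(irradiance = irradiance, voltage = voltage,
                   time = tr$time, current = tr$current)
  })
  clean_df <- dplyr::bind_rows(clean)
  peak_scale <- max(abs(clean_df$current))
  sd_abs <- config$noise_sd_rel * peak_scale
  traces <- clean_df
  if (sd_abs > 0) {
    traces$current <- traces$current + stats::rnorm(nrow(traces), 0, sd_abs)
  }

  # two-pulse recovery series (peak ratios, noise applied to the traces)
  tp <- purrr::map_dfr(config$recovery_irradiances, function(I) {
    pr1 <- .protocol_of(config, I, config$recovery_voltage)
    tpp <- two_pulse_protocol(pr1, config$intervals,
                              pulse2_s = config$pulse_s)
    tr2 <- simulate_two_pulse(config$params, tpp, dt = config$dt_two)
    p1 <- attr(tr2, "pulse1")
    if (sd_abs > 0) {
      tr2$current <- tr2$current + stats::rnorm(nrow(tr2), 0, sd_abs)
      p1$current <- p1$current + stats::rnorm(nrow(p1), 0, sd_abs)
    }
    on1 <- p1$time >= pr1$t_on & p1$time <= pr1$t_off
    base1 <- mean(p1$current[p1$time < pr1$t_on])
    peak1 <- max(abs(p1$current[on1] - base1))
    tr2 |>
      dplyr::group_by(interval) |>
      dplyr::summarise(ratio = max(abs(.data$current - base1)) / peak1,
                       .groups = "drop") |>
      dplyr::mutate(irradiance = I, voltage = config$recovery_voltage,
                    .before = 1)
  })

  truth <- .ground_truth_features(config, clean)
  structure(list(traces = traces, two_pulse = tp, truth = truth,
                 config = config),
            class = "clamp_experiment")
}

# Ground-truth features: the same extraction operations applied to the
# noiseless model output (single pulses and noiseless two-pulse ratios).
.ground_truth_features <- function(config, clean_list) {
  single <- dplyr::bind_rows(purrr::map(clean_list, function(df) {
    pr <- .protocol_of(config, df$irradiance[1], df$voltage[1])
    suppressWarnings(extract_features(df, pr))
  }))
  recov <- purrr::map_dfr(config$recovery_irradiances, function(I) {
    pr1 <- .protocol_of(config, I, config$recovery_voltage)
    tpp <- two_pulse_protocol(pr1, config$intervals, pulse2_s = config$pulse_s)
    rr <- two_pulse_peak_ratios(config$params, tpp, dt = config$dt_two)
    recovery_feature(rr, I, config$recovery_voltage)
  })
  dplyr::bind_rows(single, recov)
}

#' Generate a two-pulse series alone
#'
#' @param config a [synth_config()]; the series uses its recovery conditions.
#' @param irradiance overrides the irradiance (single condition).
#' @return A tibble with columns `interval`, `ratio` plus the trace attribute
#'   structure of [simulate_two_pulse()].
#' @export
generate_two_pulse_series <- function(config = synth_config(),
                                      irradiance = config$recovery_irradiances[1]) {
  pr1 <- .protocol_of(config, irradiance, config$recovery_voltage)
  tpp <- two_pulse_protocol(pr1, config$intervals, pulse2_s = config$pulse_s)
  tr0 <- tau_r(config$params, 0, config$recovery_voltage)
  if (max(config$intervals) < tr0) {
    warning("generate_two_pulse_series: interval grid does not span the ",
            "dark recovery time constant", call. = FALSE)
  }
  two_pulse_peak_ratios(config$params, tpp, dt = config$dt_two)
}

#' Extract the full feature set of a synthetic experiment
#'
#' Runs [extract_features()] on every (noisy) single-pulse trace and
#' [recovery_time()] on every two-pulse ratio series of a
#' [generate_clamp_traces()] result.
#'
#' @param experiment a `clamp_experiment`.
#' @param config an [extract_config()].
#' @return A feature tibble (columns `irradiance`, `voltage`, `feature`,
#'   `value`, `sigma`).
#' @export
experiment_features <- function(experiment, config = extract_config()) {
  stopifnot(inherits(experiment, "clamp_experiment"))
  sc <- experiment$config
  single <- experiment$traces |>
    dplyr::group_by(.data$irradiance, .data$voltage) |>
    dplyr::group_map(function(df, key) {
      pr <- .protocol_of(sc, key$irradiance, key$voltage)
      suppressWarnings(extract_features(df, pr, config))
    }) |>
    dplyr::bind_rows()
  recov <- experiment$two_pulse |>
    dplyr::group_by(.data$irradiance, .data$voltage) |>
    dplyr::group_map(function(df, key) {
      recovery_feature(df, key$irradiance, key$voltage)
    }) |>
    dplyr::bind_rows()
  dplyr::bind_rows(single, recov)
}

#' Write / read a feature table as CSV
#'
#' Columns `irradiance_W_m2`, `voltage_mV`, `feature`, `value`, `sigma`.
#'
#' @param features a feature tibble.
#' @param path file path.
#' @return `path` (write) or the feature tibble (read).
#' @export
write_features <- function(features, path) {
  out <- dplyr::rename(features, irradiance_W_m2 = "irradiance",
                       voltage_mV = "voltage")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::rename(irradiance = "irradiance_W_m2", voltage = "voltage_mV")
}

#' Write / read a photocurrent trace as CSV with a JSON sidecar
#'
#' The trace goes to `<path>` with header `time_s,current`; the stimulus
#' metadata goes to `<path>.json`.
#'
#' @param trace a trace tibble from [photocurrent()] (attribute `"protocol"`
#'   used for the sidecar) or any data frame with `time`/`current`.
#' @param path CSV path.
#' @param protocol optional [clamp_protocol()] overriding the attribute.
#' @param mode conductance units of the generating parameter set.
#' @return `path` (write); a trace tibble with a `"protocol"` attribute (read).
#' @export
write_trace <- function(trace, path, protocol = attr(trace, "protocol"),
                        mode = "density") {
  readr::write_csv(tibble::tibble(time_s = trace$time,
                                  current = trace$current), path)
  if (!is.null(protocol)) {
    jsonlite::write_json(
      list(irradiance_W_m2 = protocol$irradiance,
           voltage_mV = protocol$voltage,
           t_on_s = protocol$t_on, t_off_s = protocol$t_off,
           conductance_units = if (mode == "density") "mS/cm2" else "uS"),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  out <- tibble::tibble(time = df$time_s, current = df$current)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(out, "protocol") <- clamp_protocol(
      meta$irradiance_W_m2, meta$voltage_mV, t_on = meta$t_on_s,
      t_off = meta$t_off_s, t_end = max(out$time))
  }
  out
}
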