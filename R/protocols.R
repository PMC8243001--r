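#' Voltage-clamp stimulation protocol
#'
#' A rectangular optical pulse of constant irradiance delivered under voltage
#' clamp: the conditions under which the photocurrent has a closed-form
#' solution.
#'
#' @param irradiance light intensity during the pulse (W/m^2, constant).
#' @param voltage clamp potential (mV).
#' @param t_on,t_off pulse onset/offset (s), `0 <= t_on < t_off <= t_end`.
#' @param t_end end of the recorded trace (s).
#' @return An object of class `clamp_protocol`.
#' @export
clamp_protocol <- function(irradiance, voltage, t_on = 0.05, t_off = t_on + 0.5,
                           t_end = t_off + 0.3) {
  stopifnot(is.finite(irradiance), is.finite(voltage),
            is.finite(t_on), is.finite(t_off), is.finite(t_end))
  if (irradiance < 0) stop("clamp_protocol: irradiance must be >= 0", call. = FALSE)
  if (!(t_on >= 0 && t_on < t_off && t_off <= t_end)) {
    stop("clamp_protocol: need 0 <= t_on < t_off <= t_end", call. = FALSE)
  }
  structure(list(irradiance = irradiance, voltage = voltage,
                 t_on = t_on, t_off = t_off, t_end = t_end),
            class = "clamp_protocol")
}

#' Two-pulse recovery protocol
#'
#' A first conditioning pulse, a variable dark gap, and a second test pulse,
#' used to measure dark recovery of the transient peak.
#'
#' @param pulse1 a [clamp_protocol()] describing the conditioning pulse (its
#'   `t_end` is ignored; the gap starts at its `t_off`).
#' @param intervals strictly increasing dark gaps (s), all `> 0`.
#' @param pulse2_s duration of the test pulse (s).
#' @return An object of class `two_pulse_protocol`.
#' @export
two_pulse_protocol <- function(pulse1, intervals, pulse2_s = pulse1$t_off - pulse1$t_on) {
  stopifnot(inherits(pulse1, "clamp_protocol"))
  if (length(intervals) < 1 || any(intervals <= 0) ||
      any(diff(intervals) <= 0)) {
    stop("two_pulse_protocol: intervals must be strictly increasing and > 0",
         call. = FALSE)
  }
  if (pulse2_s <= 0) stop("two_pulse_protocol: pulse2_s must be > 0", call. = FALSE)
  structure(list(pulse1 = pulse1, intervals = as.numeric(intervals),
                 pulse2_s = pulse2_s),
            class = "two_pulse_protocol")
}

#' Pulse-train stimulation protocol
#'
#' A periodic rectangular light train described by irradiance, pulse repetition
#' frequency and duty cycle, applied from time zero for `stim_s` seconds and
#' followed by darkness until `total_s`.
#'
#' @param irradiance light intensity during the on phases (W/m^2).
#' @param prf_hz pulse repetition frequency (Hz).
#' @param duty on-fraction of each period, in `(0, 1]`.
#' @param stim_s stimulation duration (s).
#' @param total_s total simulated time (s), `>= stim_s`.
#' @return An object of class `pulse_train_protocol`.
#' @export
pulse_train_protocol <- function(irradiance, prf_hz, duty, stim_s,
                                 total_s = stim_s + 1) {
  stopifnot(is.finite(irradiance), irradiance >= 0, prf_hz > 0,
            stim_s > 0, total_s >= stim_s)
  if (duty <= 0 || duty > 1) {
    stop("pulse_train_protocol: duty must lie in (0, 1]", call. = FALSE)
  }
  structure(list(irradiance = irradiance, prf_hz = prf_hz, duty = duty,
                 stim_s = stim_s, total_s = total_s),
            class = "pulse_train_protocol")
}

#' Light on/off segments of a protocol
#'
#' Flattens a protocol into consecutive constant-irradiance segments
#' `(t0, t1, irradiance)`, the representation used by the piecewise solvers.
#'
#' @param protocol a [clamp_protocol()] or [pulse_train_protocol()].
#' @return A tibble with columns `t0`, `t1`, `irradiance` (times in s).
#' @export
light_segments <- function(protocol) {
  if (inherits(protocol, "clamp_protocol")) {
    seg <- tibble::tibble(
      t0 = c(0, protocol$t_on, protocol$t_off),
      t1 = c(protocol$t_on, protocol$t_off, protocol$t_end),
      irradiance = c(0, protocol$irradiance, 0)
    )
    return(dplyr::filter(seg, .data$t1 > .data$t0))
  }
  if (inherits(protocol, "pulse_train_protocol")) {
    period <- 1 / protocol$prf_hz
    on_len <- protocol$duty * period
    starts <- seq(0, protocol$stim_s - 1e-12, by = period)
    t0 <- sort(c(starts, pmin(starts + on_len, protocol$stim_s)))
    t0 <- unique(c(t0, protocol$stim_s))
    t0 <- t0[t0 < protocol$total_s]
    t1 <- c(t0[-1], protocol$total_s)
    irr <- ifelse((t0 - period * floor(t0 / period + 1e-12)) < on_len - 1e-12 &
                    t0 < protocol$stim_s, protocol$irradiance, 0)
    seg <- tibble::tibble(t0 = t0, t1 = t1, irradiance = irr)
    return(dplyr::filter(seg, .data$t1 > .data$t0 + 1e-12))
  }
  stop("light_segments: unsupported protocol class", call. = FALSE)
}
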