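# Dependency functions of the double two-state opsin model.
#
# All irradiance dependencies are logistic in log10(I); the I = 0 case is
# defined by the limit of the logistic (the light-driven terms vanish).
# Exponent arguments are clamped to avoid overflow in exp().

.clamp_exp <- function(x) exp(pmin(pmax(x, -700), 700))

# logistic of log10(I) rising with I: 0 at I = 0, 1 at I -> Inf
.log10_logistic <- function(I, mid, slope) {
  out <- numeric(length(I))
  pos <- I > 0
  out[pos] <- 1 / (1 + .clamp_exp((mid - log10(I[pos])) / slope))
  out
}

.combine_tau <- function(tau_i, tau_v, scheme) {
  if (scheme == "product") tau_i * tau_v else 1 / (1 / tau_i + 1 / tau_v)
}

.tau_voltage <- function(V, p) p[1] / (1 + .clamp_exp(-(V - p[2]) / p[3]))

#' Open-gate time constant
#'
#' The time constant of the open fraction `O` as a function of irradiance and
#' membrane potential. The irradiance part is a falling logistic of log10
#' irradiance with dark limit `tauO_I[3]`; the voltage part is a logistic in
#' `V`; the two are combined by a product or a reciprocal sum according to
#' `params$combine_O`.
#'
#' @param params an [opsin_params()] object.
#' @param irradiance irradiance (W/m^2), vectorized, `>= 0`.
#' @param voltage membrane potential (mV), vectorized.
#' @return Time constant(s) in seconds, strictly positive.
#' @export
tau_o <- function(params, irradiance, voltage) {
  .check_iv(irradiance, voltage)
  p <- params$tauO_I
  # p3 / (1 + exp((p1 + log10 I)/p2)): falls from p3 (dark) towards 0
  tau_i <- rep(p[3], length(irradiance))
  pos <- irradiance > 0
  tau_i[pos] <- p[3] / (1 + .clamp_exp((p[1] + log10(irradiance[pos])) / p[2]))
  tau_v <- .tau_voltage(voltage, params$tauO_V)
  .combine_tau(tau_i, tau_v, params$combine_O)
}

#' Adaptation-gate time constant
#'
#' Time constant of the dark-adaptation factor `R`. The irradiance part is a
#' biphasic falling logistic: `p1 * (1 - p2*L(p3,p4) - (1-p2)*L(p5,p6))` with
#' `L` a rising logistic of log10 irradiance, so it equals `p1` in the dark
#' and tends to zero at saturating light. Combination with the voltage
#' logistic follows `params$combine_R`.
#'
#' @inheritParams tau_o
#' @return Time constant(s) in seconds.
#' @export
tau_r <- function(params, irradiance, voltage) {
  .check_iv(irradiance, voltage)
  p <- params$tauR_I
  tau_i <- p[1] * (1 - p[2] * .log10_logistic(irradiance, p[3], p[4]) -
                     (1 - p[2]) * .log10_logistic(irradiance, p[5], p[6]))
  tau_v <- .tau_voltage(voltage, params$tauR_V)
  .combine_tau(tau_i, tau_v, params$combine_R)
}

#' Open-state equilibrium
#'
#' Equilibrium open fraction, a rising logistic of log10 irradiance with
#' midpoint `10^Oinf[1]` W/m^2; zero in the dark.
#'
#' @inheritParams tau_o
#' @return Fraction(s) in `[0, 1]`.
#' @export
o_inf <- function(params, irradiance) {
  stopifnot(all(is.finite(irradiance)), all(irradiance >= 0))
  .log10_logistic(irradiance, params$Oinf[1], params$Oinf[2])
}

#' Adaptation equilibrium
#'
#' Equilibrium of the dark-adaptation factor: `1` in the dark, falling to
#' `1 - Rinf[3]` at saturating light.
#'
#' @inheritParams tau_o
#' @return Fraction(s) in `[1 - Rinf[3], 1]`.
#' @export
r_inf <- function(params, irradiance) {
  stopifnot(all(is.finite(irradiance)), all(irradiance >= 0))
  1 - params$Rinf[3] * .log10_logistic(irradiance, params$Rinf[1], params$Rinf[2])
}

#' Rectified driving force
#'
#' Returns `D(V) = G(V) * (V - E)` in its algebraically cancelled form
#' `Grect[1] * (1 - Grect[2] * exp(-(V - E)/Grect[3]))` (no 0/0 at the
#' reversal potential). Without a rectification function it is the ohmic
#' `V - E`.
#'
#' @inheritParams tau_o
#' @return Driving force(s), mV-scaled.
#' @export
driving_force <- function(params, voltage) {
  stopifnot(all(is.finite(voltage)))
  if (is.null(params$Grect)) return(voltage - params$E)
  p <- params$Grect
  if (p[3] == 0) stop("driving_force: Grect decay constant must be non-zero",
                      call. = FALSE)
  p[1] * (1 - p[2] * .clamp_exp(-(voltage - params$E) / p[3]))
}

#' Rectification function G(V)
#'
#' The raw rectification factor `D(V) / (V - E)`, exposed for constraint
#' checking only (it has a removable singularity at `V = E`, where the limit
#' `Grect[1] * Grect[2] / Grect[3]` is returned). Currents are always computed
#' through [driving_force()].
#'
#' @inheritParams tau_o
#' @return G(V) values; `1` for parameter sets without rectification.
#' @export
rectification <- function(params, voltage) {
  if (is.null(params$Grect)) return(rep(1, length(voltage)))
  dv <- voltage - params$E
  out <- driving_force(params, voltage) / dv
  at_e <- abs(dv) < 1e-9
  out[at_e] <- params$Grect[1] * params$Grect[2] / params$Grect[3]
  out
}

.check_iv <- function(irradiance, voltage) {
  if (!all(is.finite(irradiance)) || !all(is.finite(voltage))) {
    stop("irradiance and voltage must be finite", call. = FALSE)
  }
  if (any(irradiance < 0)) stop("irradiance must be >= 0", call. = FALSE)
}

#' Gating-state time derivatives
#'
#' First-order relaxation of both gates towards their equilibria:
#' `dO/dt = (O_inf - O)/tau_O`, `dR/dt = (R_inf - R)/tau_R`.
#'
#' @param state numeric length 2, `c(O, R)`, both in `[0, 1]`.
#' @inheritParams tau_o
#' @return Numeric length 2: `c(dO/dt, dR/dt)` in 1/s.
#' @export
state_derivatives <- function(state, params, irradiance, voltage) {
  if (length(state) != 2 || any(!is.finite(state)) ||
      any(state < 0) || any(state > 1)) {
    stop("state must be c(O, R) with both in [0, 1]", call. = FALSE)
  }
  c((o_inf(params, irradiance) - state[1]) / tau_o(params, irradiance, voltage),
    (r_inf(params, irradiance) - state[2]) / tau_r(params, irradiance, voltage))
}

# Closed-form gating trajectories for a single rectangular pulse.
# Returns list(O, R) over `times`; init applies at t_on; state held at init
# before the pulse.
.gating_closed_form <- function(params, protocol, times, init = c(0, 1)) {
  I <- protocol$irradiance
  V <- protocol$voltage
  oi <- o_inf(params, I); ri <- r_inf(params, I)
  to_on <- tau_o(params, I, V); tr_on <- tau_r(params, I, V)
  to_off <- tau_o(params, 0, V); tr_off <- tau_r(params, 0, V)

  O <- rep(init[1], length(times)); R <- rep(init[2], length(times))
  on <- times >= protocol$t_on & times <= protocol$t_off
  tt <- times[on] - protocol$t_on
  O[on] <- oi - (oi - init[1]) * exp(-tt / to_on)
  R[on] <- ri - (ri - init[2]) * exp(-tt / tr_on)

  dur <- protocol$t_off - protocol$t_on
  O_end <- oi - (oi - init[1]) * exp(-dur / to_on)
  R_end <- ri - (ri - init[2]) * exp(-dur / tr_on)
  off <- times > protocol$t_off
  ts <- times[off] - protocol$t_off
  O[off] <- O_end * exp(-ts / to_off)
  R[off] <- 1 - (1 - R_end) * exp(-ts / tr_off)
  list(O = O, R = R, O_end = O_end, R_end = R_end)
}

#' Closed-form voltage-clamp photocurrent
#'
#' Evaluates the analytical solution of the double two-state model under
#' voltage clamp and a rectangular optical pulse: both gates follow piecewise
#' mono-exponential trajectories, relaxing towards the lit equilibria with
#' `tau(I, V)` during the pulse and back to the dark state (`O -> 0`,
#' `R -> 1`) with `tau(0, V)` afterwards. The on-branch is evaluated on
#' `[t_on, t_off]` inclusive, so the plateau read-out equals the current at
#' `t_off` exactly.
#'
#' @param params an [opsin_params()] object.
#' @param protocol a [clamp_protocol()].
#' @param times sample times (s); defaults to a regular grid at `dt`.
#' @param dt sample interval (s) used when `times` is `NULL`.
#' @param init gating state `c(O, R)` at pulse onset; `c(0, 1)` is fully
#'   dark-adapted.
#' @return A tibble with columns `time`, `current`, `O`, `R`. Current units
#'   are uA/cm^2 in density mode and nA in absolute mode. The stimulus
#'   metadata is attached as attribute `"protocol"`.
#' @export
#' @examples
#' p <- opsin_fixture("rsrs_final")
#' tr <- photocurrent(p, clamp_protocol(3162, -60))
#' range(tr$current)
photocurrent <- function(params, protocol, times = NULL, dt = 1.5e-4,
                         init = c(0, 1)) {
  params <- validate_opsin_params(params)
  stopifnot(inherits(protocol, "clamp_protocol"))
  if (length(init) != 2 || any(init < 0) || any(init > 1)) {
    stop("photocurrent: init must be c(O, R) within [0, 1]", call. = FALSE)
  }
  if (is.null(times)) times <- seq(0, protocol$t_end, by = dt)
  if (any(times < 0) || any(times > protocol$t_end + 1e-12)) {
    stop("photocurrent: times must lie within [0, t_end]", call. = FALSE)
  }
  g <- .gating_closed_form(params, protocol, times, init)
  d <- driving_force(params, protocol$voltage)
  out <- tibble::tibble(time = times,
                        current = params$g * d * g$O * g$R,
                        O = g$O, R = g$R)
  attr(out, "protocol") <- protocol
  out
}

#' Simulate the clamp photocurrent by ODE integration
#'
#' Integrates the two gating equations with `deSolve::lsoda()` under voltage
#' clamp, for a rectangular pulse protocol or an arbitrary nonnegative light
#' waveform. For rectangular pulses this agrees with [photocurrent()] to
#' solver tolerance and serves as its cross-check.
#'
#' @inheritParams photocurrent
#' @param light either `NULL` (use the protocol's rectangular pulse,
#'   integrated piecewise between the light edges) or a function `light(t)`
#'   returning irradiance in W/m^2.
#' @param voltage clamp potential (mV); only needed with a `light` function.
#' @param t_end trace end (s); only needed with a `light` function.
#' @param rtol,atol solver tolerances.
#' @return A tibble with columns `time`, `current`, `O`, `R`.
#' @export
simulate_clamp_ode <- function(params, protocol = NULL, light = NULL,
                               voltage = NULL, t_end = NULL, times = NULL,
                               dt = 1.5e-4, init = c(0, 1),
                               rtol = 1e-8, atol = 1e-10) {
  params <- validate_opsin_params(params)
  if (is.null(light)) {
    stopifnot(inherits(protocol, "clamp_protocol"))
    V <- protocol$voltage
    if (is.null(times)) times <- seq(0, protocol$t_end, by = dt)
    segs <- light_segments(protocol)
    state <- c(O = init[1], R = init[2])
    pieces <- vector("list", nrow(segs))
    for (k in seq_len(nrow(segs))) {
      tt <- times[times >= segs$t0[k] - 1e-12 & times <= segs$t1[k] + 1e-12]
      tt <- sort(unique(c(segs$t0[k], tt, segs$t1[k])))
      I <- segs$irradiance[k]
      oi <- o_inf(params, I); ri <- r_inf(params, I)
      to <- tau_o(params, I, V); tr <- tau_r(params, I, V)
      rhs <- function(t, y, parms) {
        list(c((oi - y[1]) / to, (ri - y[2]) / tr))
      }
      sol <- deSolve::lsoda(state, tt, rhs, parms = NULL,
                            rtol = rtol, atol = atol)
      if (attr(sol, "istate")[1] < 0) {
        stop("simulate_clamp_ode: solver failed near t = ",
             signif(sol[nrow(sol), 1], 6), " s", call. = FALSE)
      }
      state <- c(O = sol[nrow(sol), 2], R = sol[nrow(sol), 3])
      keep <- sol[, 1] %in% times
      pieces[[k]] <- sol[keep, , drop = FALSE]
    }
    sol <- do.call(rbind, pieces)
    sol <- sol[!duplicated(sol[, 1]), , drop = FALSE]
  } else {
    stopifnot(is.function(light), !is.null(voltage), !is.null(t_end))
    V <- voltage
    if (is.null(times)) times <- seq(0, t_end, by = dt)
    rhs <- function(t, y, parms) {
      I <- max(light(t), 0)
      list(c((o_inf(params, I) - y[1]) / tau_o(params, I, V),
             (r_inf(params, I) - y[2]) / tau_r(params, I, V)))
    }
    sol <- deSolve::lsoda(c(O = init[1], R = init[2]), times, rhs,
                          parms = NULL, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("simulate_clamp_ode: solver failed near t = ",
           signif(sol[nrow(sol), 1], 6), " s", call. = FALSE)
    }
  }
  O <- pmin(pmax(sol[, 2], 0), 1)
  R <- pmin(pmax(sol[, 3], 0), 1)
  tibble::tibble(time = sol[, 1],
                 current = params$g * driving_force(params, V) * O * R,
                 O = O, R = R)
}

#' Post-stimulus decay constraint
#'
#' For the current to decay monotonically back to baseline after the pulse,
#' the lit equilibrium of the adaptation gate must satisfy
#' `R_inf(I) > 1 - tau_R(0,V) / (tau_R(0,V) + tau_O(0,V))` (otherwise the
#' post-pulse dark re-adaptation of `R` can transiently outgrow the closing of
#' `O`). The constraint is checked pointwise on an irradiance/voltage grid.
#'
#' @param params an [opsin_params()] object.
#' @param irradiances irradiance grid (W/m^2).
#' @param voltages voltage grid (mV).
#' @return A list with `pass` (logical), `margin` (worst value of
#'   `R_inf - bound`; positive means satisfied strictly) and a tibble `grid`
#'   of per-point margins.
#' @export
check_decay_constraint <- function(params, irradiances, voltages) {
  params <- validate_opsin_params(params)
  grid <- tidyr::expand_grid(irradiance = irradiances, voltage = voltages)
  tr0 <- tau_r(params, rep(0, nrow(grid)), grid$voltage)
  to0 <- tau_o(params, rep(0, nrow(grid)), grid$voltage)
  bound <- 1 - tr0 / (tr0 + to0)
  margin <- r_inf(params, grid$irradiance) - bound
  grid$margin <- margin
  list(pass = all(margin > 0), margin = min(margin), grid = grid)
}

#' Closed-form two-pulse simulation
#'
#' Simulates a conditioning pulse from the fully dark-adapted state, an
#' analytic dark-gap relaxation (`O` decays with `tau_O(0,V)`, `R` recovers
#' with `tau_R(0,V)`), and a test pulse started from the end-of-gap state,
#' for each inter-pulse interval of the protocol.
#'
#' @param params an [opsin_params()] object.
#' @param protocol a [two_pulse_protocol()].
#' @param dt sample interval (s); recovery experiments are conventionally
#'   sampled coarser than single pulses.
#' @return A tibble with columns `interval`, `time`, `current`, one pulse-2
#'   trace per interval with `time` relative to the test-pulse onset. The
#'   shared conditioning trace is attached as attribute `"pulse1"`.
#' @export
simulate_two_pulse <- function(params, protocol, dt = 1e-3) {
  params <- validate_opsin_params(params)
  stopifnot(inherits(protocol, "two_pulse_protocol"))
  p1 <- protocol$pulse1
  V <- p1$voltage
  tr1 <- photocurrent(params, p1, dt = dt)
  g1 <- .gating_closed_form(params, p1, p1$t_off)
  to0 <- tau_o(params, 0, V)
  tr0 <- tau_r(params, 0, V)
  d <- driving_force(params, V)
  out <- purrr::map_dfr(protocol$intervals, function(gap) {
    O0 <- g1$O_end * exp(-gap / to0)
    R0 <- 1 - (1 - g1$R_end) * exp(-gap / tr0)
    p2 <- clamp_protocol(p1$irradiance, V, t_on = 0,
                         t_off = protocol$pulse2_s,
                         t_end = protocol$pulse2_s)
    tt <- seq(0, protocol$pulse2_s, by = dt)
    g2 <- .gating_closed_form(params, p2, tt, init = c(O0, R0))
    tibble::tibble(interval = gap, time = tt,
                   current = params$g * d * g2$O * g2$R)
  })
  attr(out, "pulse1") <- tr1
  attr(out, "protocol") <- protocol
  out
}

#' Peak-ratio recovery series
#'
#' Ratio of the second to the first transient peak magnitude as a function of
#' the dark interval, measured on the sampled two-pulse traces (both peaks are
#' grid maxima of the baseline-subtracted magnitude, as in the experimental
#' read-out).
#'
#' @inheritParams simulate_two_pulse
#' @return A tibble with columns `interval`, `ratio`.
#' @export
two_pulse_peak_ratios <- function(params, protocol, dt = 1e-3) {
  traces <- simulate_two_pulse(params, protocol, dt = dt)
  p1 <- attr(traces, "pulse1")
  on1 <- p1$time >= protocol$pulse1$t_on & p1$time <= protocol$pulse1$t_off
  peak1 <- max(abs(p1$current[on1]))
  traces |>
    dplyr::group_by(.data$interval) |>
    dplyr::summarise(ratio = max(abs(.data$current)) / peak1,
                     .groups = "drop")
}
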