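#' Regular-spiking cortical neuron configuration
#'
#' Loads the single-compartment regular-spiking (RS) cortical pyramidal model
#' shipped as a fixture: leak, transient sodium and delayed-rectifier
#' potassium currents with threshold-shifted Traub kinetics, and the slow
#' non-inactivating M-type potassium current responsible for spike-frequency
#' adaptation. Conductances are densities (mS/cm^2), so no membrane area is
#' needed.
#'
#' @param path optional path to an alternative neuron JSON file with the same
#'   schema.
#' @return A list of class `neuron_config`.
#' @export
rs_neuron <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "neuron", "rs_pospischil.json",
                        package = "opsin22", mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- structure(list(
    C = raw$C_uF_cm2, g_leak = raw$g_leak_mS_cm2, E_leak = raw$E_leak_mV,
    g_Na = raw$g_Na_mS_cm2, E_Na = raw$E_Na_mV, g_Kd = raw$g_Kd_mS_cm2,
    g_M = raw$g_M_mS_cm2, E_K = raw$E_K_mV, V_T = raw$V_T_mV,
    tau_max = raw$tau_max_ms, name = raw$name %||% "rs"),
    class = "neuron_config")
  if (any(!vapply(cfg[c("C", "g_leak", "g_Na", "g_Kd", "g_M")], is.numeric,
                  logical(1))) ||
      cfg$C <= 0 || cfg$g_leak < 0 || cfg$g_Na < 0 || cfg$g_Kd < 0 ||
      cfg$g_M < 0) {
    stop("rs_neuron: invalid neuron configuration", call. = FALSE)
  }
  cfg
}

# gate steady states of the RS model at potential V (rates per ms)
.rs_gates_inf <- function(V, neuron) {
  vtrap <- function(x, s) ifelse(abs(x / s) < 1e-6,
                                 s * (1 - x / (2 * s)),
                                 x / (exp(x / s) - 1))
  vm <- V - neuron$V_T
  am <- 0.32 * vtrap(-(vm - 13), 4); bm <- 0.28 * vtrap(vm - 40, 5)
  ah <- 0.128 * exp(-(vm - 17) / 18); bh <- 4 / (1 + exp(-(vm - 40) / 5))
  an <- 0.032 * vtrap(-(vm - 15), 5); bn <- 0.5 * exp(-(vm - 10) / 40)
  c(m = am / (am + bm), h = ah / (ah + bh), n = an / (an + bn),
    p = 1 / (1 + exp(-(V + 35) / 10)))
}

#' Resting state of the RS neuron
#'
#' Solves the zero-current fixed point (gates at steady state, no light) by
#' root bisection on the stationary membrane equation.
#'
#' @param neuron a [rs_neuron()] configuration.
#' @return Named numeric: `V`, `m`, `h`, `n`, `p`.
#' @export
rs_resting_state <- function(neuron = rs_neuron()) {
  f <- function(V) {
    g <- .rs_gates_inf(V, neuron)
    neuron$g_leak * (V - neuron$E_leak) +
      neuron$g_Na * g["m"]^3 * g["h"] * (V - neuron$E_Na) +
      neuron$g_Kd * g["n"]^4 * (V - neuron$E_K) +
      neuron$g_M * g["p"] * (V - neuron$E_K)
  }
  V <- stats::uniroot(f, lower = -90, upper = -50, tol = 1e-10)$root
  g <- .rs_gates_inf(V, neuron)
  c(V = V, g)
}

.seg_parms <- function(I, opsin, neuron) {
  # irradiance parts of the opsin rates for a constant-intensity segment
  tau_oi <- {
    p <- opsin$tauO_I
    if (I > 0) p[3] / (1 + .clamp_exp((p[1] + log10(I)) / p[2])) else p[3]
  }
  tau_ri <- {
    p <- opsin$tauR_I
    p[1] * (1 - p[2] * .log10_logistic(I, p[3], p[4]) -
              (1 - p[2]) * .log10_logistic(I, p[5], p[6]))
  }
  has_rect <- !is.null(opsin$Grect)
  gp <- if (has_rect) opsin$Grect else c(0, 0, 1)
  c(neuron$C, neuron$g_leak, neuron$E_leak, neuron$g_Na, neuron$E_Na,
    neuron$g_Kd, neuron$g_M, neuron$E_K, neuron$V_T, neuron$tau_max,
    opsin$g, opsin$E, gp[1], gp[2], gp[3], as.numeric(has_rect),
    max(tau_oi, 1e-9), max(tau_ri, 1e-9),
    o_inf(opsin, I), r_inf(opsin, I),
    opsin$tauO_V[1], opsin$tauO_V[2], opsin$tauO_V[3],
    opsin$tauR_V[1], opsin$tauR_V[2], opsin$tauR_V[3],
    as.numeric(opsin$combine_O == "product"),
    as.numeric(opsin$combine_R == "product"))
}

#' Simulate the RS neuron driven by an opsin photocurrent
#'
#' Integrates the membrane equation, the four intrinsic gates and the two
#' opsin gates under an optical stimulation protocol. The system is solved
#' segment-wise between light edges (the irradiance is constant within a
#' segment) with `deSolve::lsoda` and a compiled right-hand side, using a
#' 100 us maximum step and relative/absolute tolerances of 1e-3/1e-6 — the
#' solver regime standard for this neuron model.
#'
#' @param opsin an [opsin_params()] in density mode (mS/cm^2).
#' @param protocol a [pulse_train_protocol()] or [clamp_protocol()] (the
#'   latter is treated as a single rectangular light pulse; the membrane is
#'   of course not clamped).
#' @param neuron a [rs_neuron()] configuration.
#' @param dt_out output sample interval (s).
#' @param rtol,atol,hmax_ms solver settings (max step in ms).
#' @param init initial state; defaults to the dark resting state with a
#'   fully dark-adapted opsin.
#' @return A tibble with columns `time` (s), `v` (mV), `o`, `r` (opsin
#'   gates) and `i_chr` (opsin current, uA/cm^2, negative inward).
#' @export
#' @examples
#' \donttest{
#' tr <- simulate_rs_neuron(opsin_fixture("rsrs_final"),
#'                          pulse_train_protocol(3162, 1, 0.5, 2, 3))
#' length(detect_spikes(tr))
#' }
simulate_rs_neuron <- function(opsin, protocol, neuron = rs_neuron(),
                               dt_out = 1e-4, rtol = 1e-3, atol = 1e-6,
                               hmax_ms = 0.1, init = NULL) {
  opsin <- validate_opsin_params(opsin)
  if (opsin$mode != "density") {
    stop("simulate_rs_neuron: opsin must be in density mode (mS/cm^2)",
         call. = FALSE)
  }
  segs <- light_segments(protocol)
  if (is.null(init)) {
    rest <- rs_resting_state(neuron)
    init <- c(rest, O = 0, R = 1)
  }
  state <- unname(init)
  pieces <- vector("list", nrow(segs))
  for (k in seq_len(nrow(segs))) {
    t0 <- segs$t0[k] * 1000; t1 <- segs$t1[k] * 1000 # ms
    tt <- unique(c(seq(t0, t1, by = dt_out * 1000), t1))
    sol <- deSolve::lsoda(
      y = state, times = tt, func = "rs22_derivs", dllname = "opsin22",
      initfunc = "rs22_init",
      parms = .seg_parms(segs$irradiance[k], opsin, neuron),
      nout = 1, outnames = "ichr",
      rtol = rtol, atol = atol, hmax = hmax_ms)
    if (attr(sol, "istate")[1] < 0) {
      stop("simulate_rs_neuron: solver failed near t = ",
           signif(sol[nrow(sol), 1] / 1000, 6), " s", call. = FALSE)
    }
    state <- unname(sol[nrow(sol), 2:8])
    pieces[[k]] <- if (k == 1) sol else sol[-1, , drop = FALSE]
  }
  sol <- do.call(rbind, pieces)
  tibble::tibble(time = sol[, 1] / 1000, v = sol[, 2],
                 o = sol[, 7], r = sol[, 8], i_chr = sol[, 9])
}

#' Detect spikes as upward zero-crossings
#'
#' Spike times are linear interpolations of upward 0 mV crossings of the
#' membrane potential, deduplicated with a 1 ms minimum inter-spike
#' separation.
#'
#' @param trace a tibble with columns `time` (s) and `v` (mV), or a numeric
#'   voltage vector with `times` supplied.
#' @param times sample times when `trace` is a bare vector.
#' @param threshold crossing level (mV).
#' @param min_isi_s minimum inter-spike separation (s).
#' @return Numeric vector of spike times (s).
#' @export
detect_spikes <- function(trace, times = NULL, threshold = 0,
                          min_isi_s = 1e-3) {
  if (is.data.frame(trace)) {
    v <- trace$v; t <- trace$time
  } else {
    v <- trace; t <- times
    if (is.null(t)) stop("detect_spikes: times required", call. = FALSE)
  }
  up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  if (!length(up)) return(numeric(0))
  frac <- (threshold - v[up]) / (v[up + 1] - v[up])
  st <- t[up] + frac * (t[up + 1] - t[up])
  # enforce the refractory rule sequentially, not pairwise
  out <- st[1]
  for (s in st[-1]) if (s - out[length(out)] >= min_isi_s) out <- c(out, s)
  out
}

#' Firing rate under an optical stimulation protocol
#'
#' The default convention counts spikes occurring during the light-on phases
#' and divides by the total on-time; `window = "total"` divides the total
#' spike count by the full protocol duration instead.
#'
#' @param spikes spike times (s) from [detect_spikes()].
#' @param protocol the [pulse_train_protocol()] (or [clamp_protocol()]) that
#'   drove the simulation.
#' @param window `"on"` (default) or `"total"`.
#' @return Firing rate in Hz.
#' @export
firing_rate <- function(spikes, protocol, window = c("on", "total")) {
  window <- match.arg(window)
  segs <- light_segments(protocol)
  on <- segs[segs$irradiance > 0, ]
  if (window == "total") {
    total <- max(segs$t1)
    if (total <= 0) stop("firing_rate: zero-duration protocol", call. = FALSE)
    return(length(spikes) / total)
  }
  on_time <- sum(on$t1 - on$t0)
  if (on_time <= 0) stop("firing_rate: protocol has zero on-time", call. = FALSE)
  n_on <- sum(vapply(spikes, function(s) any(s >= on$t0 & s < on$t1),
                     logical(1)))
  n_on / on_time
}
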