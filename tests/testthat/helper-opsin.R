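# Shared helpers: deterministic random parameter draws inside the published
# bounds and small synthetic configurations used across tests.

# A flat-voltage, product-combined parameter set whose dark time constants
# are exactly (tauO_dark, tauR_dark); handy for analytic checks.
flat_params <- function(tauO_dark = 0.02, tauR_dark = 5, depth = 0.77,
                        g = 1, Grect = c(10, 1.25, 45)) {
  opsin_params(
    g = g, E = 0,
    tauO_I = c(1.8, 1.2, tauO_dark),
    tauO_V = c(2, 0, 1e6),   # logistic ~ 1/(1+exp(0)) = 0.5 -> 2*0.5 = 1
    tauR_I = c(tauR_dark, 0.56, -1.6, 0.9, 2, 0.11),
    tauR_V = c(2, 0, 1e6),
    Oinf = c(3.4, 0.6), Rinf = c(2, 0.12, depth), Grect = Grect,
    combine_O = "product", combine_R = "product")
}

# Draw a random parameter set uniformly within the published bounds, with
# mild rejection so the voltage-clamp test protocol is numerically
# meaningful (time constants between 0.1 ms and 60 s at the probe condition,
# non-negligible equilibrium opening).
random_opsin_params <- function(probe_I = 1000, probe_V = -60) {
  b <- opsin_bounds("chr2")
  lb <- pmax(b$lb, ifelse(b$positive, 1e-3, b$lb))
  repeat {
    v <- stats::runif(nrow(b), lb, b$ub)
    p <- tryCatch(
      opsin_params(g = 1, E = 0,
                   tauO_I = v[1:3], tauO_V = v[4:6], tauR_I = v[7:12],
                   tauR_V = v[13:15], Oinf = v[16:17], Rinf = v[18:20],
                   Grect = v[21:23],
                   combine_O = sample(c("product", "reciprocal_sum"), 1),
                   combine_R = sample(c("product", "reciprocal_sum"), 1)),
      error = function(e) NULL)
    if (is.null(p)) next
    taus <- c(tau_o(p, probe_I, probe_V), tau_o(p, 0, probe_V),
              tau_r(p, probe_I, probe_V), tau_r(p, 0, probe_V))
    if (any(!is.finite(taus)) || any(taus < 1e-4) || any(taus > 60)) next
    if (o_inf(p, probe_I) < 0.05) next
    return(p)
  }
}

# small noiseless synthetic design for fast tests
small_synth_config <- function(seed = 1, noise = 0) {
  synth_config(
    irradiances = 10^c(2, 3, 4),
    voltages = c(-80, -60, 0, 40),
    recovery_irradiances = 10^c(3, 4),
    intervals = c(0.5, 1.5, 3, 5, 8, 13, 18),
    noise_sd_rel = noise, seed = seed)
}
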