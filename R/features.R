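#' Mono-exponential fit by multistart Levenberg-Marquardt
#'
#' Fits `y = A * exp(-(t - t[1]) / tau) + C` by bounded least squares
#' (`minpack.lm::nls.lm`, analytic Jacobian, function/parameter tolerances
#' 1e-12) from a deterministic set of starting points: a data-driven start
#' (log-linear regression of the offset-corrected decay) followed by time
#' constants log-spaced between the sample interval and three spans, with
#' amplitude and offset seeded from the data. The best start by residual
#' norm wins; exact ties are broken by lexicographic order of the parameter
#' vector.
#'
#' @param t strictly increasing sample times (>= 4 samples).
#' @param y values.
#' @param n_starts number of starting points (default 10).
#' @return An object of class `monoexp_fit`: list with `A`, `tau`, `C`,
#'   `rss`, `fitted`, `t0`.
#' @export
#' @examples
#' t <- seq(0, 0.4, by = 0.002)
#' f <- fit_monoexp(t, 2 * exp(-t / 0.05) + 0.5)
#' c(f$A, f$tau, f$C)
fit_monoexp <- function(t, y, n_starts = 10) {
  if (length(t) < 4) stop("fit_monoexp: need at least 4 samples", call. = FALSE)
  if (any(diff(t) <= 0)) stop("fit_monoexp: t must be strictly increasing",
                              call. = FALSE)
  if (length(y) != length(t) || !all(is.finite(y))) {
    stop("fit_monoexp: y must be finite and match t", call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    stop("fit_monoexp: constant input is degenerate", call. = FALSE)
  }
  t0 <- t[1]
  tt <- t - t0
  span <- tt[length(tt)]
  dt <- min(diff(t))

  resid_fn <- function(par) {
    par[1] * exp(-tt / par[2]) + par[3] - y
  }
  jac_fn <- function(par) {
    e <- exp(-tt / par[2])
    cbind(e, par[1] * e * tt / par[2]^2, 1)
  }

  C0 <- mean(utils::tail(y, max(2L, length(y) %/% 20)))
  A0 <- y[1] - C0
  # data-driven start: closed-form slope of log|y - C0| on t
  taus <- numeric(0)
  dev <- abs(y - C0)
  ok <- dev > max(dev) * 1e-3
  if (sum(ok) >= 3) {
    xo <- tt[ok]; yo <- log(dev[ok])
    sl <- sum((xo - mean(xo)) * (yo - mean(yo))) / sum((xo - mean(xo))^2)
    if (is.finite(sl) && sl < 0) taus <- -1 / sl
  }
  grid <- exp(seq(log(max(dt, span * 1e-3)), log(3 * span),
                  length.out = n_starts))
  if (length(taus)) {
    taus <- c(taus, grid[seq_len(max(n_starts - 1L, 0L))])
  } else {
    taus <- grid
  }

  best <- NULL
  for (tau0 in taus) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(A0, tau0, C0), fn = resid_fn, jac = jac_fn,
        lower = c(-Inf, dt * 1e-3, -Inf), upper = c(Inf, Inf, Inf),
        control = minpack.lm::nls.lm.control(
          ftol = 1e-12, ptol = 1e-12, maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15 ||
        (abs(rss - best$rss) <= 1e-15 &&
         .lex_less(fit$par, best$par))) {
      best <- list(par = fit$par, rss = rss)
    }
  }
  if (is.null(best)) stop("fit_monoexp: no start converged", call. = FALSE)
  structure(
    list(A = best$par[1], tau = best$par[2], C = best$par[3],
         rss = best$rss, t0 = t0,
         fitted = best$par[1] * exp(-tt / best$par[2]) + best$par[3]),
    class = "monoexp_fit")
}

.lex_less <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  length(i) > 0 && d[i[1]] < 0
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat("<monoexp_fit> y = A exp(-(t - t0)/tau) + C\n")
  cat("  A =", format(x$A), " tau =", format(x$tau), "s  C =", format(x$C),
      " rss =", format(x$rss), "\n")
  invisible(x)
}

#' Feature-extraction configuration
#'
#' @param guard number of samples dropped after each segment edge (pulse
#'   onset, peak, pulse offset) before the mono-exponential fits, provided
#'   enough samples remain; guards against edge artifacts.
#' @param plateau_frac fraction of the on-phase (from the end) averaged for
#'   the plateau estimate.
#' @param n_starts multistart count passed to [fit_monoexp()].
#' @param min_points minimum samples per fitted segment; short onset windows
#'   are extended forward to this length.
#' @param max_fit_points segments longer than this are subsampled evenly
#'   before the time-constant fit (on noiseless model traces the estimate is
#'   unchanged; used by the lean extraction inside the swarm cost).
#' @return A list of class `extract_config`.
#' @export
extract_config <- function(guard = 1L, plateau_frac = 0.05, n_starts = 10L,
                           min_points = 4L, max_fit_points = Inf) {
  stopifnot(guard >= 0, plateau_frac > 0, plateau_frac <= 0.5,
            n_starts >= 1, min_points >= 4, max_fit_points >= 10)
  structure(list(guard = as.integer(guard), plateau_frac = plateau_frac,
                 n_starts = as.integer(n_starts),
                 min_points = as.integer(min_points),
                 max_fit_points = max_fit_points),
            class = "extract_config")
}

.fit_segment_tau <- function(t, y, config) {
  if (length(t) > config$min_points + config$guard && config$guard > 0) {
    # drop the first guard samples after the edge, keeping the edge itself
    t <- t[-(1L + seq_len(config$guard))]
    y <- y[-(1L + seq_len(config$guard))]
  }
  if (length(t) > config$max_fit_points) {
    idx <- unique(round(seq(1L, length(t), length.out = config$max_fit_points)))
    t <- t[idx]; y <- y[idx]
  }
  if (length(t) < config$min_points) return(NA_real_)
  out <- tryCatch(fit_monoexp(t, y, n_starts = config$n_starts),
                  error = function(e) NULL)
  if (is.null(out)) NA_real_ else out$tau
}

# Core single-pulse feature measurement on raw vectors; shared by the
# user-facing extractor and the fast path inside the swarm cost.
# Returns c(i_peak, i_ss, i_ratio, tau_on, tau_inact, tau_off) or errors for
# unusable traces; tau_* may be NA.
.extract_core <- function(t, y, t_on, t_off, config) {
  on <- which(t >= t_on - 1e-12 & t <= t_off + 1e-12)
  if (length(on) < 4) stop("extract_features: trace contains no usable pulse",
                           call. = FALSE)
  pre <- which(t < t_on - 1e-12)
  baseline <- if (length(pre)) mean(y[pre]) else 0
  dev <- y - baseline

  ipk <- on[which.max(abs(dev[on]))]
  i_peak <- abs(dev[ipk])
  if (i_peak == 0) stop("extract_features: flat trace during pulse",
                        call. = FALSE)
  n_pl <- max(2L, ceiling(length(on) * config$plateau_frac))
  i_ss <- abs(mean(dev[utils::tail(on, n_pl)]))

  # activation: onset..peak (extended forward if the rise spans < min_points)
  on_end <- max(ipk, on[1] + config$min_points - 1L)
  on_idx <- on[on >= on[1] & on <= on_end]
  tau_on <- .fit_segment_tau(t[on_idx], dev[on_idx], config)

  # inactivation: peak..offset
  in_idx <- on[on >= ipk]
  tau_inact <- if (length(in_idx) >= config$min_points) {
    .fit_segment_tau(t[in_idx], dev[in_idx], config)
  } else NA_real_
  peak_at_edge <- length(in_idx) < config$min_points

  # deactivation: offset..end
  off_idx <- which(t >= t_off - 1e-12)
  tau_off <- if (length(off_idx) >= config$min_points) {
    .fit_segment_tau(t[off_idx], dev[off_idx], config)
  } else NA_real_

  out <- c(i_peak = i_peak, i_ss = i_ss, i_ratio = i_ss / i_peak,
           tau_on = tau_on, tau_inact = tau_inact, tau_off = tau_off)
  attr(out, "peak_at_edge") <- peak_at_edge
  out
}

#' Extract single-pulse photocurrent features
#'
#' Measures the six single-pulse target features from a voltage-clamp trace:
#' the transient peak `i_peak` (maximal deflection from the pre-pulse
#' baseline), the plateau `i_ss` (mean magnitude over the last fraction of the
#' on-phase), their ratio `i_ratio`, and the activation, inactivation and
#' deactivation time constants from mono-exponential fits on the
#' onset-to-peak, peak-to-offset and post-pulse segments.
#'
#' @param trace a data frame with columns `time` (s) and `current`.
#' @param protocol the [clamp_protocol()] that produced the trace.
#' @param config an [extract_config()].
#' @return A tibble with columns `irradiance`, `voltage`, `feature`, `value`,
#'   `sigma` (sigma is `NA`; it carries measurement uncertainty when known).
#'   Time constants that cannot be fit (e.g. the peak sits at the pulse edge)
#'   are returned as `NA` with a warning.
#' @export
extract_features <- function(trace, protocol, config = extract_config()) {
  stopifnot(is.data.frame(trace), all(c("time", "current") %in% names(trace)),
            inherits(protocol, "clamp_protocol"))
  vals <- .extract_core(trace$time, trace$current, protocol$t_on,
                        protocol$t_off, config)
  if (isTRUE(attr(vals, "peak_at_edge"))) {
    warning("extract_features: peak at pulse edge, inactivation unavailable",
            call. = FALSE)
  }
  tibble::tibble(
    irradiance = protocol$irradiance,
    voltage = protocol$voltage,
    feature = names(vals),
    value = as.numeric(vals),
    sigma = NA_real_
  )
}

#' Recovery time from a two-pulse peak-ratio series
#'
#' The recovery time is the dark interval at which the second transient peak
#' reaches `1 - exp(-1)` (about 63.2%) of the first. The sampled
#' (interval, ratio) series is interpolated with a monotone piecewise-cubic
#' spline and the crossing found by root bisection.
#'
#' @param intervals dark gaps (s), increasing.
#' @param ratios peak ratios `I_p2 / I_p1` in `(0, 1]`.
#' @return Recovery time in seconds.
#' @export
recovery_time <- function(intervals, ratios) {
  if (length(intervals) < 2 || length(ratios) != length(intervals)) {
    stop("recovery_time: need >= 2 matching intervals and ratios",
         call. = FALSE)
  }
  if (any(ratios <= 0) || any(ratios > 1 + 1e-9)) {
    stop("recovery_time: ratios must lie in (0, 1]", call. = FALSE)
  }
  thr <- 1 - exp(-1)
  hit <- which(abs(ratios - thr) < 1e-12)
  if (length(hit)) return(intervals[hit[1]])
  if (all(ratios > thr)) {
    stop("recovery_time: recovery faster than the interval grid",
         call. = FALSE)
  }
  if (all(ratios < thr)) {
    stop("recovery_time: peak not recovered within the interval grid",
         call. = FALSE)
  }
  f <- stats::splinefun(intervals, ratios, method = "monoH.FC")
  stats::uniroot(function(x) f(x) - thr,
                 lower = min(intervals), upper = max(intervals),
                 tol = 1e-10)$root
}

#' Measure the recovery feature of a two-pulse ratio series
#'
#' Convenience wrapper returning the recovery time as a feature row.
#'
#' @param ratios a tibble with columns `interval`, `ratio` (e.g. from
#'   [two_pulse_peak_ratios()]).
#' @param irradiance,voltage the stimulation condition the series was
#'   measured at (metadata for the feature row).
#' @return A one-row feature tibble (`feature = "tau_recov"`).
#' @export
recovery_feature <- function(ratios, irradiance, voltage) {
  tibble::tibble(
    irradiance = irradiance, voltage = voltage, feature = "tau_recov",
    value = recovery_time(ratios$interval, ratios$ratio), sigma = NA_real_)
}
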