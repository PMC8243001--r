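# Core model: dependency functions, closed-form solution, ODE cross-check,
# decay constraint, two-pulse behaviour.

test_that("dependency functions reproduce hand-evaluated values", {
  p <- opsin_fixture("rsrs_final")

  # dark limits
  expect_equal(tau_r(p, 0, -60) * 0 + p$tauR_I[1], 10)
  # intensity part of tau_O in the dark is its third parameter; combined with
  # the voltage logistic 23.14/(1+exp(-(-60+0.39)/13.19)) ~ 0.2495 s by
  # reciprocal sum: (1/0.021 + 1/0.2495)^-1 ~ 0.0194 s
  expect_equal(tau_o(p, 0, -60), 0.01937, tolerance = 1e-3)

  # logistic midpoint and limits of the open equilibrium
  expect_equal(o_inf(p, 0), 0)
  expect_equal(o_inf(p, 10^p$Oinf[1]), 0.5)
  expect_equal(o_inf(p, 5500), 0.6414, tolerance = 1e-3)
  expect_gt(o_inf(p, 1e7), o_inf(p, 1e3)) # monotone increasing

  # adaptation equilibrium: fully dark-adapted at I = 0, floor 1 - depth
  expect_equal(r_inf(p, 0), 1)
  expect_equal(r_inf(p, 1e12), 1 - p$Rinf[3], tolerance = 1e-6)
  mm <- opsin_fixture("mm_final")
  expect_equal(r_inf(mm, 1e12), 0.0013, tolerance = 1e-6)

  # rectified driving force and its zero crossing at E + p3*log(p2)
  expect_equal(driving_force(p, -60), -41.04, tolerance = 1e-3)
  v0 <- p$E + p$Grect[3] * log(p$Grect[2])
  expect_equal(driving_force(p, v0), 0, tolerance = 1e-9)
  expect_equal(v0, 9.93, tolerance = 1e-2)
  # p2 = 1 makes the reversal truly ohmic
  q <- p; q$Grect[2] <- 1
  expect_equal(driving_force(q, q$E), 0)
  # no rectification -> plain V - E
  expect_equal(driving_force(mm, -60), -60 - mm$E)
})

test_that("state derivatives vanish at equilibrium and push off the dark state", {
  p <- opsin_fixture("rsrs_final")
  eq <- c(o_inf(p, 500), r_inf(p, 500))
  expect_equal(state_derivatives(eq, p, 500, -60), c(0, 0), tolerance = 1e-12)
  expect_equal(state_derivatives(c(0, 1), p, 0, -60), c(0, 0))
  d <- state_derivatives(c(0, 1), p, 500, -60)
  expect_gt(d[1], 0)
  expect_lt(d[2], 0)
  expect_error(state_derivatives(c(-0.1, 1), p, 500, -60), "0, 1")
})

test_that("closed form matches the ODE route and respects gating bounds", {
  p <- opsin_fixture("rsrs_final")
  pr <- clamp_protocol(3162, -60)
  cf <- photocurrent(p, pr)
  expect_true(all(cf$current[cf$time < pr$t_on] == 0))
  ode <- simulate_clamp_ode(p, pr)
  expect_lt(max(abs(cf$current - ode$current)), 1e-4 * max(abs(cf$current)))

  # a handful of random draws here; the 100-draw sweep lives in the
  # acceptance suite
  set.seed(42)
  for (k in 1:5) {
    q <- random_opsin_params()
    prk <- clamp_protocol(10^stats::runif(1, 2, 4), stats::runif(1, -80, 40),
                          t_on = 0.02, t_off = 0.25, t_end = 0.45)
    cfk <- photocurrent(q, prk)
    odek <- simulate_clamp_ode(q, prk)
    expect_lt(max(abs(cfk$current - odek$current)),
              1e-4 * max(abs(cfk$current), 1e-12))
    expect_true(all(cfk$O >= 0 & cfk$O <= 1 & cfk$R >= 0 & cfk$R <= 1))
  }
})

test_that("scaling invariance: g and the rectification gain trade off exactly", {
  p <- opsin_fixture("rsrs_final")
  q <- normalize_conductance(p, g = 9.91)
  expect_equal(q$g * q$Grect[1], p$g * p$Grect[1])
  pr <- clamp_protocol(1000, -40)
  expect_equal(photocurrent(p, pr)$current, photocurrent(q, pr)$current,
               tolerance = 1e-12)
})

test_that("current returns to baseline monotonically when the decay condition holds", {
  p <- opsin_fixture("rsrs_final")
  pr <- clamp_protocol(3162, -60, t_on = 0.01, t_off = 0.51, t_end = 1.5)
  expect_true(check_decay_constraint(p, 3162, -60)$pass)
  cf <- photocurrent(p, pr)
  post <- abs(cf$current[cf$time > pr$t_off + 1e-3])
  expect_true(all(diff(post) <= 1e-12))
  expect_lt(post[length(post)], 1e-6 * max(abs(cf$current)))
})

test_that("ODE route supports arbitrary light waveforms", {
  p <- opsin_fixture("rsrs_final")
  # darkness: flat zero current
  dark <- simulate_clamp_ode(p, light = function(t) 0, voltage = -60,
                             t_end = 0.2, dt = 1e-3)
  expect_true(all(dark$current == 0))
  # ramp: O is nondecreasing while it stays below the momentary equilibrium
  ramp <- simulate_clamp_ode(p, light = function(t) 1e4 * t, voltage = -60,
                             t_end = 0.3, dt = 1e-3)
  below <- ramp$O < o_inf(p, pmax(1e4 * ramp$time, 0))
  expect_true(all(diff(ramp$O)[below[-length(below)]] >= -1e-12))
})

test_that("decay constraint margins match direct evaluation", {
  # tau_R(0,V) = 5 s, tau_O(0,V) = 0.02 s -> bound = 1 - 5/5.02 ~ 0.003984
  p <- flat_params(tauO_dark = 0.02, tauR_dark = 5, depth = 0.99)
  chk <- check_decay_constraint(p, 1e12, 0)
  bound <- 1 - 5 / 5.02
  expect_equal(chk$grid$margin, (1 - 0.99) - bound, tolerance = 1e-6)
  expect_true(chk$pass) # floor 0.01 > 0.003984

  # tau_O -> 0 makes the bound vanish
  p2 <- flat_params(tauO_dark = 1e-9, tauR_dark = 5, depth = 0.999)
  expect_gt(check_decay_constraint(p2, 1e12, 0)$margin, -1e-6)

  # R_inf exactly at the bound fails (strict inequality)
  p3 <- flat_params(tauO_dark = 0.02, tauR_dark = 5, depth = 1 - bound)
  expect_false(check_decay_constraint(p3, 1e12, 0)$pass)
})

test_that("two-pulse peak ratio approaches full recovery and the plateau restart", {
  p <- opsin_fixture("rsrs_final")
  pr <- clamp_protocol(3162, -60, t_on = 0.02, t_off = 0.52, t_end = 0.6)
  tpp <- two_pulse_protocol(pr, intervals = c(1e-4, 60))
  rr <- two_pulse_peak_ratios(p, tpp)
  feats <- extract_features(photocurrent(p, pr, dt = 1e-3), pr)
  i_ratio <- feats$value[feats$feature == "i_ratio"]
  # interval -> 0: second peak restarts from the plateau state
  expect_equal(rr$ratio[1], i_ratio, tolerance = 0.05)
  # interval >> tau_R(0,V): full recovery
  expect_equal(rr$ratio[2], 1, tolerance = 0.01)
})

test_that("protocol validation rejects malformed stimuli", {
  expect_error(clamp_protocol(-5, -60), "irradiance")
  expect_error(clamp_protocol(100, -60, t_on = 0.5, t_off = 0.2), "t_on")
  expect_error(two_pulse_protocol(clamp_protocol(100, -60), c(2, 1)),
               "increasing")
  expect_error(pulse_train_protocol(100, 1, duty = 1.5, stim_s = 1), "duty")
  # pulse-train segmentation covers the stimulation window
  segs <- light_segments(pulse_train_protocol(50, 2, 0.25, 1, 1.5))
  expect_equal(sum(segs$t1 - segs$t0), 1.5)
  expect_equal(sum((segs$t1 - segs$t0)[segs$irradiance > 0]), 0.25)
})
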