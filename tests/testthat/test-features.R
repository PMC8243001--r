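# Feature extraction: mono-exponential fitting, single-pulse features,
# recovery interpolation.

test_that("fit_monoexp recovers exact and noisy exponentials", {
  t <- seq(0, 0.4, by = 0.002)
  f <- fit_monoexp(t, 2 * exp(-t / 0.05) + 0.5)
  expect_equal(f$A, 2, tolerance = 1e-6)
  expect_equal(f$tau, 0.05, tolerance = 1e-6)
  expect_equal(f$C, 0.5, tolerance = 1e-6)

  set.seed(11)
  tn <- seq(0, 0.4, length.out = 200)
  yn <- 2 * exp(-tn / 0.05) + 0.5 + rnorm(200, 0, 0.01)
  fn <- fit_monoexp(tn, yn)
  expect_equal(fn$tau, 0.05, tolerance = 0.05)

  expect_error(fit_monoexp(t, rep(1, length(t))), "degenerate")
  expect_error(fit_monoexp(t[1:3], c(1, 2, 3)), "4 samples")
  expect_error(fit_monoexp(c(0, 0.1, 0.1, 0.2), c(1, 2, 3, 4)), "increasing")
})

test_that("single-pulse extraction matches the generating model", {
  p <- opsin_fixture("rsrs_final")
  pr <- clamp_protocol(3162, -60)
  tr <- photocurrent(p, pr)
  f <- extract_features(tr, pr)
  v <- setNames(f$value, f$feature)

  expect_equal(unname(v["tau_off"]), tau_o(p, 0, -60), tolerance = 0.1)
  expect_equal(unname(v["tau_inact"]), tau_r(p, 3162, -60), tolerance = 0.1)
  expect_gt(v["i_ratio"], 0)
  expect_lt(v["i_ratio"], 1)
  # plateau estimate agrees with the closed-form current at pulse offset
  expect_equal(unname(v["i_ss"]),
               abs(tr$current[which.min(abs(tr$time - pr$t_off))]),
               tolerance = 0.01)

  # i_ratio is invariant under rescaling of the current
  tr2 <- tr; tr2$current <- 7.3 * tr2$current
  f2 <- extract_features(tr2, pr)
  expect_equal(f2$value[f2$feature == "i_ratio"],
               unname(v["i_ratio"]), tolerance = 1e-9)

  # repeated extraction is deterministic
  expect_identical(extract_features(tr, pr), f)

  # a trace with no pulse samples errors out
  flat <- tibble::tibble(time = seq(0, 0.01, 1e-3), current = 0)
  expect_error(extract_features(flat, pr), "pulse")
})

test_that("recovery time interpolates the 63% crossing", {
  expect_equal(recovery_time(c(1, 3, 8), c(0.4, 1 - exp(-1), 0.9)), 3)
  r <- recovery_time(c(1, 3, 8), c(0.3, 0.5, 0.95))
  expect_gt(r, 3); expect_lt(r, 8)
  expect_error(recovery_time(c(1, 3, 8), c(0.99, 0.995, 1)), "faster")
  expect_error(recovery_time(c(1, 3, 8), c(0.1, 0.2, 0.3)), "not recovered")
  expect_error(recovery_time(1, 0.5), ">= 2")
})

test_that("round trip: extracted constants satisfy the feature relations", {
  # conditions: time-to-peak >> tau_O, pulse long enough for the plateau,
  # recovery intervals spanning tau_R(0,V)
  p <- opsin_fixture("rsrs_final")
  I <- 3162; V <- -60
  pr <- clamp_protocol(I, V, t_on = 0.02, t_off = 0.52, t_end = 0.8)
  f <- extract_features(photocurrent(p, pr), pr)
  v <- setNames(f$value, f$feature)
  expect_equal(unname(v["tau_on"]), tau_o(p, I, V), tolerance = 0.1)
  expect_equal(unname(v["tau_off"]), tau_o(p, 0, V), tolerance = 0.1)
  expect_equal(unname(v["tau_inact"]), tau_r(p, I, V), tolerance = 0.1)

  tpp <- two_pulse_protocol(pr, c(0.5, 1, 2, 3.5, 5, 7, 10, 14, 18))
  rr <- two_pulse_peak_ratios(p, tpp)
  t_rec <- recovery_time(rr$interval, rr$ratio)
  pred <- tau_r(p, 0, V) * (1 - log(1 / (1 - v[["i_ratio"]])))
  expect_equal(t_rec, pred, tolerance = 0.1)
})
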