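# Synthetic experiment generator: determinism, noise model, ground truth.

test_that("noiseless traces equal the closed form and seeds control the noise", {
  cfg0 <- small_synth_config(seed = 2, noise = 0)
  ex0 <- generate_clamp_traces(cfg0)
  one <- dplyr::filter(ex0$traces, irradiance == 1000, voltage == -60)
  pr <- clamp_protocol(1000, -60, t_on = cfg0$t_on,
                       t_off = cfg0$t_on + cfg0$pulse_s,
                       t_end = cfg0$t_on + cfg0$pulse_s + cfg0$post_s)
  cf <- photocurrent(cfg0$params, pr, dt = cfg0$dt)
  expect_identical(one$current, cf$current)

  exA <- generate_clamp_traces(small_synth_config(seed = 2, noise = 0.01))
  exB <- generate_clamp_traces(small_synth_config(seed = 2, noise = 0.01))
  exC <- generate_clamp_traces(small_synth_config(seed = 3, noise = 0.01))
  expect_identical(exA$traces$current, exB$traces$current)
  expect_false(identical(exA$traces$current, exC$traces$current))
  # noise scale: 1% of the grid-maximal peak
  resid <- exA$traces$current - ex0$traces$current
  expect_equal(stats::sd(resid), 0.01 * max(abs(ex0$traces$current)),
               tolerance = 0.05)
})

test_that("extraction on noiseless output recovers the ground truth features", {
  ex <- generate_clamp_traces(small_synth_config(seed = 4, noise = 0))
  got <- experiment_features(ex)
  j <- dplyr::inner_join(
    dplyr::select(ex$truth, "irradiance", "voltage", "feature",
                  truth = "value"),
    dplyr::select(got, "irradiance", "voltage", "feature", got = "value"),
    by = c("irradiance", "voltage", "feature"))
  expect_gt(nrow(j), 20)
  expect_lt(max(abs(j$got / j$truth - 1), na.rm = TRUE), 0.02)
})

test_that("two-pulse series has the right limits and warns off short grids", {
  cfg <- small_synth_config(seed = 6)
  rr <- generate_two_pulse_series(cfg, irradiance = 1e4)
  expect_true(all(diff(rr$ratio) > 0))       # monotone recovery
  expect_lt(rr$ratio[1], 1)
  expect_gt(max(rr$ratio), 1 - exp(-1))      # grid spans the recovery time

  short <- synth_config(intervals = c(0.1, 0.2), noise_sd_rel = 0)
  expect_warning(generate_two_pulse_series(short), "span")
})

test_that("recovery times in the ground truth follow the rescaling relation", {
  cfg <- small_synth_config(seed = 8)
  truth <- generate_clamp_traces(cfg)$truth
  wide <- tidyr::pivot_wider(
    dplyr::select(truth, "irradiance", "voltage", "feature", "value"),
    names_from = "feature", values_from = "value")
  rec <- dplyr::filter(wide, !is.na(.data$tau_recov))
  p <- cfg$params
  pred <- tau_r(p, 0, rec$voltage) * (1 - log(1 / (1 - rec$i_ratio)))
  expect_lt(max(abs(rec$tau_recov / pred - 1)), 0.1)
})
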