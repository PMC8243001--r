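# Regular-spiking neuron with the opsin current: resting stability, spike
# detection, firing-rate conventions, solver robustness.

test_that("the dark neuron rests quietly and matches its opsin-free dynamics", {
  p <- opsin_fixture("rsrs_final")
  dark <- simulate_rs_neuron(p, pulse_train_protocol(0, 1, 0.5, 1, 1.2))
  expect_length(detect_spikes(dark), 0)
  expect_lt(max(abs(dark$v - dark$v[1])), 0.5)

  # negligible opsin conductance under light reproduces the dark dynamics
  tiny <- p; tiny$g <- 1e-9
  lit <- simulate_rs_neuron(tiny, pulse_train_protocol(5000, 1, 0.5, 1, 1.2))
  expect_lt(max(abs(lit$v - dark$v)), 1e-3)
})

test_that("strong illumination elicits spikes and rate grows with irradiance", {
  p <- opsin_fixture("rsrs_final")
  tr <- simulate_rs_neuron(p, pulse_train_protocol(1e4, 1 / 0.3, 1, 0.3, 0.8))
  expect_gte(length(detect_spikes(tr)), 1)

  rates <- sapply(c(100, 1000, 10000), function(I) {
    pr <- pulse_train_protocol(I, 2, 0.5, 1, 1.2)
    firing_rate(detect_spikes(simulate_rs_neuron(p, pr)), pr)
  })
  expect_true(all(diff(rates) >= 0))
})

test_that("spike detection applies the refractory rule and interpolation", {
  t <- seq(0, 0.05, by = 1e-4)
  flat <- tibble::tibble(time = t, v = rep(-65, length(t)))
  expect_length(detect_spikes(flat), 0)

  # two clean crossings 10 ms apart
  v <- rep(-65, length(t))
  v[t > 0.010 & t < 0.012] <- 20
  v[t > 0.020 & t < 0.022] <- 20
  expect_length(detect_spikes(tibble::tibble(time = t, v = v)), 2)

  # chattering double-crossing within 0.5 ms collapses to one spike
  v2 <- rep(-65, length(t))
  v2[t > 0.0100 & t < 0.0102] <- 20
  v2[t > 0.0104 & t < 0.0106] <- 20
  expect_length(detect_spikes(tibble::tibble(time = t, v = v2)), 1)
})

test_that("firing-rate conventions: on-phase versus whole-window", {
  pr <- pulse_train_protocol(100, 1, 0.5, 2, 3)
  spikes_on <- seq(0.05, 0.45, by = 0.01) # 41 spikes in the first on phase
  expect_equal(firing_rate(spikes_on, pr), 41 / 1)
  expect_equal(firing_rate(spikes_on, pr, window = "total"), 41 / 3)
  expect_equal(firing_rate(numeric(0), pr), 0)
  # off-phase spikes change only the whole-window figure
  spikes_mix <- c(spikes_on, 0.7, 0.8)
  expect_equal(firing_rate(spikes_mix, pr), 41)
  expect_equal(firing_rate(spikes_mix, pr, window = "total"), 43 / 3)
})

test_that("rates are stable under solver tolerance tightening", {
  p <- opsin_fixture("rsrs_final")
  pr <- pulse_train_protocol(3162, 1, 0.5, 2, 2.5)
  n1 <- length(detect_spikes(simulate_rs_neuron(p, pr)))
  n2 <- length(detect_spikes(simulate_rs_neuron(p, pr, rtol = 1e-6,
                                                atol = 1e-9)))
  expect_lte(abs(n1 - n2), 1)
})

test_that("density-mode guard and fixture validation", {
  mm <- opsin_fixture("mm_final")
  expect_error(simulate_rs_neuron(mm, pulse_train_protocol(100, 1, 0.5, 1)),
               "density")
  cfg <- rs_neuron()
  expect_equal(cfg$C, 1)
  expect_equal(cfg$tau_max, 608)
  rest <- rs_resting_state(cfg)
  expect_lt(rest["V"], -65); expect_gt(rest["V"], -80)
})
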