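# Strength-duration analysis: TAC, Hill-Lapicque and mapping fits, the
# closed-form irradiance-domain transfer, threshold bracketing.

test_that("temporal average current of simple current shapes", {
  # rectangular inward current of amplitude A during PD, zero after -> A
  t <- seq(0, 1.1, by = 1e-4)
  tr <- tibble::tibble(time = t, i_chr = ifelse(t <= 0.1, -2, 0))
  expect_equal(temporal_average_current(tr, 0.1), 2, tolerance = 1e-2)

  # a post-pulse tail raises the TAC above the on-phase mean
  tr2 <- tibble::tibble(time = t,
                        i_chr = ifelse(t <= 0.1, -2, -2 * exp(-(t - 0.1) / 0.05)))
  expect_gt(temporal_average_current(tr2, 0.1), 2)

  # fixed integral: halving PD doubles the TAC
  expect_equal(temporal_average_current(tr, 0.05),
               2 * temporal_average_current(tr, 0.1), tolerance = 1e-2)

  expect_error(temporal_average_current(tr[t < 0.5, ], 0.1), "shorter")
})

test_that("Hill-Lapicque fit: round trip, chronaxie definition, limits", {
  pd <- 10^seq(-3, 0, length.out = 12)
  tac <- 0.5 / (1 - exp(-pd * log(2) / 0.04))
  hl <- fit_hill_lapicque(pd, tac)
  expect_equal(hl$rheobase, 0.5, tolerance = 1e-3)
  expect_equal(hl$chronaxie, 0.04, tolerance = 1e-3)
  expect_gt(hl$adj_r2, 0.9999)
  # at PD = chronaxie the threshold is twice the rheobase
  expect_equal(hl$rheobase / (1 - exp(-hl$chronaxie * log(2) / hl$chronaxie)),
               2 * hl$rheobase)
  expect_error(fit_hill_lapicque(c(0.1, 0.2, 0.3, 0.4), 1:4), "decade")
})

test_that("power mapping: round trip, identity, degeneracy", {
  tac <- c(0.5, 1, 2, 4, 8, 16)
  irr <- 2 * tac^1.5 + 1
  mp <- fit_power_mapping(tac, irr)
  expect_equal(mp$a, 2, tolerance = 1e-3)
  expect_equal(mp$b, 1.5, tolerance = 1e-3)
  expect_equal(mp$c, 1, tolerance = 1e-2)

  ident <- fit_power_mapping(tac, tac)
  expect_equal(ident$a, 1, tolerance = 1e-3)
  expect_equal(ident$b, 1, tolerance = 1e-3)
  expect_equal(ident$c, 0, tolerance = 1e-3)

  expect_error(fit_power_mapping(tac, rep(5, 6)), "degenerate")
})

test_that("irradiance-domain transfer is exact for analytic mappings", {
  hl <- list(rheobase = 1, chronaxie = 0.04)
  # identity mapping leaves both quantities unchanged
  out <- irradiance_rheo_chron(list(a = 1, b = 1, c = 0), hl)
  expect_equal(out$rheobase, 1)
  expect_equal(out$chronaxie, 0.04)
  # pure scaling (a = 2, b = 1, c = 0)
  out2 <- irradiance_rheo_chron(list(a = 2, b = 1, c = 0), hl)
  expect_equal(out2$rheobase, 2)
  expect_equal(out2$chronaxie, 0.04)
  # a negative offset can push (2*I_rheo - c)/a out of the domain
  expect_error(irradiance_rheo_chron(list(a = 1, b = 1, c = -3), hl),
               "must be > 0")
})

test_that("threshold irradiance brackets the spike boundary and is monotone in PD", {
  p <- opsin_fixture("rsrs_final")
  thr_long <- threshold_irradiance(0.3, p, rel_tol = 0.02)
  thr_short <- threshold_irradiance(0.01, p, rel_tol = 0.02)
  expect_gt(thr_short, thr_long)

  spikes_at <- function(I, pd) {
    pr <- pulse_train_protocol(I, 1 / pd, 1, pd, pd + 1)
    length(detect_spikes(simulate_rs_neuron(p, pr))) >= 1
  }
  expect_true(spikes_at(thr_long * 1.05, 0.3))
  expect_false(spikes_at(thr_long / 1.05, 0.3))

  # an opsin too weak to drive a spike reports an out-of-range error
  weak <- p; weak$g <- 1e-9
  expect_error(threshold_irradiance(0.1, weak, upper = 1e4), "upper")
})

test_that("the irradiance-domain chronaxie matches a direct search on the composite curve", {
  # the closed-form transfer must invert the mapping+Lapicque composition:
  # locate the duration where the composite threshold equals twice the
  # irradiance rheobase and compare
  hl <- list(rheobase = 0.5, chronaxie = 0.045)
  mp <- list(a = 8, b = 1.3, c = 1.7)
  out <- irradiance_rheo_chron(mp, hl)
  comp <- function(pd) {
    tac <- hl$rheobase / (1 - exp(-pd * log(2) / hl$chronaxie))
    mp$a * tac^mp$b + mp$c
  }
  pd_star <- uniroot(function(pd) comp(pd) - 2 * out$rheobase,
                     c(1e-5, 10), tol = 1e-12)$root
  expect_equal(out$chronaxie, pd_star, tolerance = 1e-6)
})
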