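# Staged fitting: target construction, time-constant and equilibrium
# recovery, swarm refinement behaviour, pipeline plumbing.

test_that("time-constant targets apply the recovery rescaling", {
  f <- tibble::tibble(
    irradiance = c(1000, 1000, 1000, 1000, 1000, 1000, 1000),
    voltage = -60,
    feature = c("i_peak", "i_ss", "i_ratio", "tau_on", "tau_inact",
                "tau_off", "tau_recov"),
    value = c(10, 4, 0.4, 2e-4, 0.02, 0.02, 3), sigma = NA_real_)
  tg <- approximate_time_constant_targets(f)
  # tau_recov / (1 - ln(1/(1 - 0.4))) = 3 / 0.48917 ~ 6.133
  dark_r <- tg$value[tg$gate == "tau_r" & tg$irradiance == 0]
  expect_equal(dark_r, 3 / (1 - log(1 / 0.6)), tolerance = 1e-9)
  expect_equal(dark_r, 6.133, tolerance = 1e-3)
  # lit rows pass straight through
  expect_equal(tg$value[tg$gate == "tau_o" & tg$irradiance > 0], 2e-4)
  expect_equal(tg$value[tg$gate == "tau_r" & tg$irradiance > 0], 0.02)

  # ratio -> 0 limit: no rescaling
  f2 <- f; f2$value[f2$feature == "i_ratio"] <- 1e-9
  tg2 <- approximate_time_constant_targets(f2)
  expect_equal(tg2$value[tg2$gate == "tau_r" & tg2$irradiance == 0], 3,
               tolerance = 1e-6)

  # ratio past 1 - exp(-1) makes the denominator non-positive
  f3 <- f; f3$value[f3$feature == "i_ratio"] <- 0.7
  expect_error(approximate_time_constant_targets(f3), "invalid")

  expect_error(approximate_time_constant_targets(f[0, ]), "no features")
})

test_that("time-constant fit reproduces exact targets", {
  p <- opsin_fixture("rsrs_final")
  grid <- tidyr::expand_grid(irradiance = c(0, 10^seq(2, 4, length.out = 4)),
                             voltage = seq(-80, 40, by = 40))
  tg <- dplyr::bind_rows(
    dplyr::mutate(grid, gate = "tau_o",
                  value = tau_o(p, grid$irradiance, grid$voltage)),
    dplyr::mutate(grid, gate = "tau_r",
                  value = tau_r(p, grid$irradiance, grid$voltage)))
  cfg <- fit_config(mode = "test", n_starts_tau = 10)
  tp <- suppressWarnings(fit_time_constants(tg, cfg))
  q <- opsin_params(g = 1, E = 0, tauO_I = tp$tauO_I, tauO_V = tp$tauO_V,
                    tauR_I = tp$tauR_I, tauR_V = tp$tauR_V,
                    Oinf = p$Oinf, Rinf = p$Rinf, Grect = p$Grect)
  expect_lt(max(abs(tau_o(q, grid$irradiance, grid$voltage) /
                      tau_o(p, grid$irradiance, grid$voltage) - 1)), 0.01)
  expect_lt(max(abs(tau_r(q, grid$irradiance, grid$voltage) /
                      tau_r(p, grid$irradiance, grid$voltage) - 1)), 0.01)
})

test_that("degenerate target designs are handled", {
  p <- opsin_fixture("rsrs_final")
  # single voltage: the surface still matches the targets at that voltage
  grid1 <- tibble::tibble(irradiance = c(0, 100, 1000, 10000), voltage = -60)
  tg1 <- dplyr::bind_rows(
    dplyr::mutate(grid1, gate = "tau_o",
                  value = tau_o(p, grid1$irradiance, grid1$voltage)),
    dplyr::mutate(grid1, gate = "tau_r",
                  value = tau_r(p, grid1$irradiance, grid1$voltage)))
  expect_warning(tp1 <- fit_time_constants(tg1, fit_config(
    mode = "test", n_starts_tau = 10)), "fewer conditions")
  q1 <- opsin_params(g = 1, E = 0, tauO_I = tp1$tauO_I, tauO_V = tp1$tauO_V,
                     tauR_I = tp1$tauR_I, tauR_V = tp1$tauR_V,
                     Oinf = p$Oinf, Rinf = p$Rinf, Grect = p$Grect)
  expect_lt(max(abs(tau_o(q1, grid1$irradiance, -60) /
                      tau_o(p, grid1$irradiance, -60) - 1)), 0.02)

  # constant targets: a flat surface is representable (product scheme)
  grid2 <- tidyr::expand_grid(irradiance = c(0, 100, 1000, 10000),
                              voltage = c(-60, 0))
  tgc <- dplyr::bind_rows(
    dplyr::mutate(grid2, gate = "tau_o", value = 0.02),
    dplyr::mutate(grid2, gate = "tau_r", value = 5))
  cfgc <- fit_config(mode = "test", combine_O = "product",
                     combine_R = "product", n_starts_tau = 10)
  tpc <- suppressWarnings(fit_time_constants(tgc, cfgc))
  expect_lt(tpc$rss_o, 1e-4)
  expect_lt(tpc$rss_r, 1e-4)
})

# analytic current features of a parameter set at the given conditions
# (model outputs exactly as the step-3 objective defines them)
model_current_features <- function(p, grid, pulse_s = 0.5, dt = 1.5e-4) {
  purrr::pmap_dfr(grid, function(irradiance, voltage) {
    pr <- clamp_protocol(irradiance, voltage, t_on = 0, t_off = pulse_s,
                         t_end = pulse_s)
    tr <- photocurrent(p, pr, dt = dt)
    peak <- max(abs(tr$current))
    ss <- abs(tr$current[nrow(tr)])
    tibble::tibble(irradiance = irradiance, voltage = voltage,
                   feature = c("i_peak", "i_ss", "i_ratio"),
                   value = c(peak, ss, ss / peak), sigma = NA_real_)
  })
}

test_that("equilibrium fit recovers known parameters under constraints", {
  p <- opsin_fixture("rsrs_final")
  grid <- tidyr::expand_grid(irradiance = 10^seq(2, 4, length.out = 5),
                             voltage = seq(-80, 40, by = 20))
  feats <- model_current_features(p, grid)
  tau_params <- list(tauO_I = p$tauO_I, tauO_V = p$tauO_V,
                     tauR_I = p$tauR_I, tauR_V = p$tauR_V,
                     combine_O = p$combine_O, combine_R = p$combine_R)
  cfg <- fit_config(mode = "test", n_starts_eq = 10, pulse_s = 0.5, t_on = 0)
  eq <- suppressWarnings(fit_equilibria(tau_params, feats, cfg))
  expect_lt(abs(eq$params$Oinf[1] - p$Oinf[1]), 0.02 * abs(p$Oinf[1]))
  expect_lt(abs(eq$params$Rinf[3] - p$Rinf[3]), 0.02 * abs(p$Rinf[3]))
  expect_lt(abs(eq$params$Grect[1] * eq$params$g -
                  p$Grect[1] * p$g), 0.02 * p$Grect[1] * p$g)
  # cost is tiny relative to the weighted target scale
  w <- cfg$weights
  wide <- tidyr::pivot_wider(feats, names_from = "feature",
                             values_from = "value")
  scale <- sqrt(mean((w$peak * wide$i_peak)^2 + (w$ss * wide$i_ss)^2 +
                       (w$ratio * wide$i_ratio)^2))
  expect_lt(eq$cost, 1e-6 * scale)
  # printed saturation constraint holds on the returned parameters
  expect_gt(o_inf(eq$params, 5500), 0.6)
  expect_true(check_decay_constraint(eq$params, grid$irradiance,
                                     grid$voltage)$pass)
})

test_that("swarm refinement never degrades the intermediate point", {
  synth <- generate_clamp_traces(small_synth_config(seed = 3))
  feats <- experiment_features(synth)
  cfg <- fit_config(mode = "test", pso_particles = 12, pso_max_iter = 3,
                    intervals = synth$config$intervals,
                    recovery_irradiances = synth$config$recovery_irradiances)
  p <- synth$config$params
  ext0 <- opsin22:::.feature_cost(
    predict_features(p, feats, cfg, extract = cfg$pso_extract),
    feats, cfg$weights)
  ref <- suppressWarnings(global_refine_pso(p, feats, cfg))
  expect_lte(ref$cost, ext0 + 1e-12)
  # the returned point respects the full published bounds
  b <- opsin_bounds("chr2")
  v <- opsin22:::.pack_params(ref$params, cfg)
  expect_true(all(v >= b$lb - 1e-9 & v <= b$ub + 1e-9))
})

test_that("swarm refinement descends from a perturbed intermediate", {
  synth <- generate_clamp_traces(small_synth_config(seed = 5))
  feats <- experiment_features(synth)
  cfg <- fit_config(mode = "test", pso_particles = 25, pso_max_iter = 5,
                    intervals = synth$config$intervals,
                    recovery_irradiances = synth$config$recovery_irradiances)
  p <- synth$config$params
  pert <- p
  pert$tauO_I <- p$tauO_I * 1.05
  pert$Oinf <- p$Oinf * 1.02
  pert$Grect <- p$Grect * c(1.05, 1, 1.02)
  ext0 <- opsin22:::.feature_cost(
    predict_features(pert, feats, cfg, extract = cfg$pso_extract),
    feats, cfg$weights)
  ref <- suppressWarnings(global_refine_pso(pert, feats, cfg))
  expect_lt(ref$cost, ext0)
})

test_that("the pipeline is seed-deterministic and stage-labelled", {
  synth <- generate_clamp_traces(small_synth_config(seed = 9))
  cfg <- fit_config(mode = "test", n_starts_tau = 5, n_starts_eq = 4,
                    pso_particles = 8, pso_max_iter = 2,
                    pso_budget_s = 1e6, seed = 4)
  f1 <- suppressWarnings(fit_opsin(synth, cfg))
  f2 <- suppressWarnings(fit_opsin(synth, cfg))
  expect_equal(opsin22:::.pack_params(f1$final, cfg),
               opsin22:::.pack_params(f2$final, cfg))
  # extended cost never increases from step 3 to step 4
  expect_lte(f1$cost_final, f1$cost_intermediate_ext + 1e-12)

  # precomputed features give the same result as the raw experiment
  feats <- experiment_features(synth, cfg$extract)
  cfg2 <- cfg
  cfg2$pulse_s <- synth$config$pulse_s
  cfg2$t_on <- synth$config$t_on
  cfg2$post_s <- synth$config$post_s
  cfg2$dt_single <- synth$config$dt
  cfg2$dt_two <- synth$config$dt_two
  cfg2$intervals <- synth$config$intervals
  cfg2$recovery_irradiances <- synth$config$recovery_irradiances
  cfg2$recovery_voltage <- synth$config$recovery_voltage
  f3 <- suppressWarnings(fit_opsin(feats, cfg2))
  expect_equal(opsin22:::.pack_params(f1$final, cfg),
               opsin22:::.pack_params(f3$final, cfg))

  expect_error(fit_opsin(feats[0, ], cfg), "feature")
  expect_error(fit_opsin(1:3, cfg), "clamp_experiment")
})
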