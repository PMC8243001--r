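# Goodness-of-fit metric table.

mk_feats <- function(values, features = names(values), I = 100, V = -60) {
  tibble::tibble(irradiance = I, voltage = V, feature = features,
                 value = unname(values), sigma = NA_real_)
}

test_that("metrics vanish for a perfect fit and match hand arithmetic", {
  t <- mk_feats(c(i_peak = 2, i_ss = 1))
  expect_true(all(goodness_of_fit(t, t)$value[
    !is.na(goodness_of_fit(t, t)$value)] == 0))

  # one condition, one feature, y = 3 vs t = 2
  m1 <- mk_feats(c(i_peak = 3)); t1 <- mk_feats(c(i_peak = 2))
  g1 <- goodness_of_fit(m1, t1)
  expect_equal(g1$value[g1$metric == "RMSE" & g1$scope == "i_peak"], 1)
  expect_equal(g1$value[g1$metric == "RMSNE" & g1$scope == "i_peak"], 0.5)

  # grouped scope: errors 3 and 4 on two features of one condition -> 5
  m2 <- mk_feats(c(i_peak = 5, i_ss = 6)); t2 <- mk_feats(c(i_peak = 2, i_ss = 2))
  g2 <- goodness_of_fit(m2, t2)
  expect_equal(g2$value[g2$metric == "RMSE" & g2$scope == "all"], 5)
  expect_equal(g2$value[g2$metric == "RMSE" & g2$scope == "I_all"], 5)
})

test_that("weight conventions: RMSWE with unit weights is RMSE, RMSZE with unit sigma", {
  t <- dplyr::bind_rows(mk_feats(c(i_peak = 2, tau_on = 0.01), I = 100),
                        mk_feats(c(i_peak = 4, tau_on = 0.02), I = 1000))
  t$sigma <- 1
  m <- t; m$value <- m$value * 1.3
  g <- goodness_of_fit(m, t, weights = list(peak = 1, ss = 1, ratio = 1,
                                            on = 1, inact = 1, off = 1,
                                            recov = 1))
  for (sc in c("i_peak", "tau_on", "all")) {
    rmse <- g$value[g$metric == "RMSE" & g$scope == sc]
    expect_equal(g$value[g$metric == "RMSWE" & g$scope == sc], rmse)
    expect_equal(g$value[g$metric == "RMSZE" & g$scope == sc], rmse)
  }
  # tau_all only aggregates the time constants
  expect_equal(g$value[g$metric == "RMSE" & g$scope == "tau_all"],
               sqrt(mean((c(0.01, 0.02) * 0.3)^2)))
})

test_that("metrics are invariant under condition reordering and flag zero targets", {
  t <- dplyr::bind_rows(mk_feats(c(i_peak = 2), I = 100),
                        mk_feats(c(i_peak = 4), I = 1000),
                        mk_feats(c(i_peak = 8), I = 10000))
  m <- t; m$value <- c(2.5, 3.5, 9)
  g_fwd <- goodness_of_fit(m, t)
  g_rev <- goodness_of_fit(m[3:1, ], t[c(2, 3, 1), ])
  expect_equal(g_fwd$value, g_rev$value)

  t0 <- t; t0$value[1] <- 0
  expect_warning(g0 <- goodness_of_fit(m, t0), "RMSNE")
  expect_equal(g0$value[g0$metric == "RMSNE" & g0$scope == "i_peak"],
               sqrt(mean((c(3.5 / 4, 9 / 8) - 1)^2)))
})
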