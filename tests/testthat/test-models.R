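test_that("model forms reproduce their closed-form limits", {
  p5 <- model_params(5, D_MACRO = 0.078, L = 0.110, tau = 0.0016)
  expect_equal(eval_dapp(p5, 1e-9), 0.078 + 0.110^2 / (12 * 0.0016),
    tolerance = 1e-6
  )
  # the confined term vanishes as L^2/(12 t) at long times
  expect_equal(eval_dapp(p5, 1e6), 0.078, tolerance = 1e-7)

  p1 <- model_params(1, D_MACRO = 0.3)
  expect_equal(eval_dapp(p1, c(1e-4, 1e-2, 1)), rep(0.3, 3))

  # corral series sums to zero at long times: 4 t D_app -> L^2/3
  p4 <- model_params(4, L = 0.2, tau = 5e-3)
  expect_equal(4 * 5 * eval_dapp(p4, 5), 0.2^2 / 3, tolerance = 1e-12)

  # anomalous model with alpha = 1 reduces to free diffusion
  p2 <- model_params(2, D_MACRO = 0.4, alpha = 1)
  expect_equal(eval_dapp(p2, c(1e-3, 1)), rep(0.4, 2))
})

test_that("model 5 nests model 3 and D_app decays monotonically", {
  t <- 10^seq(-4, 0, length.out = 40)
  p5 <- model_params(5, D_MACRO = 0, L = 0.11, tau = 1.6e-3)
  p3 <- model_params(3, L = 0.11, tau = 1.6e-3)
  expect_equal(eval_dapp(p5, t), eval_dapp(p3, t))

  for (p in list(
    p3, model_params(4, L = 0.11, tau = 1.6e-3),
    model_params(5, D_MACRO = 0.078, L = 0.11, tau = 1.6e-3),
    model_params(6, D_MACRO = 0.078, L = 0.11, tau = 1.6e-3, beta = 0.7)
  )) {
    d <- eval_dapp(p, t)
    expect_true(all(diff(d) <= 1e-12))
  }
})

test_that("series truncation is stable", {
  t <- 10^seq(-5, -1, length.out = 30)
  for (p in list(
    model_params(4, L = 0.11, tau = 1.6e-3),
    model_params(6, D_MACRO = 0.078, L = 0.11, tau = 1.6e-3, beta = 0.6)
  )) {
    a <- eval_dapp(p, t, k_max = 199L)
    b <- eval_dapp(p, t, k_max = 399L)
    expect_lt(max(abs(a - b) / pmax(abs(a), 1e-300)), 1e-10)
  }
})

test_that("corrected prediction applies blur and noise terms exactly", {
  t_lag <- 1 / 1800
  p <- model_params(5,
    D_MACRO = 0.078, L = 0.11, tau = 1.6e-3,
    R = 0, delta_xy = 0
  )
  n <- 1:50
  expect_equal(corrected_prediction(p, n, t_lag), eval_dapp(p, n * t_lag))

  # immobile with noise only: delta^2/t_lag at n = 1
  pim <- model_params(1, D_MACRO = 0, R = 1 / 6, delta_xy = 0.035)
  expect_equal(corrected_prediction(pim, 1, t_lag), 0.035^2 * 1800)

  # blur factors (1 - 2R/n) at n = 1 and n = 6 for R = 1/6
  pfree <- model_params(1, D_MACRO = 1, R = 1 / 6, delta_xy = 0)
  expect_equal(corrected_prediction(pfree, 1, t_lag), 2 / 3)
  expect_equal(corrected_prediction(pfree, 6, t_lag), 17 / 18)

  # algebraic inverse recovers eval_dapp to machine precision
  p$R <- 1 / 6
  p$delta_xy <- 0.0357
  y <- corrected_prediction(p, n, t_lag)
  back <- (y - p$delta_xy^2 / (n * t_lag)) / (1 - 2 * p$R / n)
  expect_equal(back, eval_dapp(p, n * t_lag), tolerance = 1e-14)
})

test_that("derived quantities match the printed confinement arithmetic", {
  d <- derive_quantities(model_params(5, D_MACRO = 0.078, L = 0.110, tau = 0.0016))
  expect_equal(d$tau_confinement, 0.110^2 / (4 * 0.078))
  expect_equal(d$tau_confinement, 0.039, tolerance = 0.01)
  expect_equal(d$S_conf, d$D_micro / 0.078)

  # STED-FCS side: L = 150 nm, D_MACRO = 0.4 -> tau_confinement ~ 14 ms
  d2 <- derive_quantities(model_params(5, D_MACRO = 0.4, L = 0.150, tau = 4.7e-3))
  expect_equal(d2$tau_confinement, 0.01406, tolerance = 1e-3)

  # S_conf ~ 9 for D_mu = 0.70, D_MACRO = 0.078
  expect_equal(0.70 / 0.078, 8.97, tolerance = 1e-3)

  d3 <- derive_quantities(model_params(4, L = 0.1, tau = 1e-3))
  expect_true(d3$infinite_confinement)
  expect_identical(d3$S_conf, Inf)

  # model 6 short-range coefficient includes beta^2
  d6 <- derive_quantities(
    model_params(6, D_MACRO = 0.05, L = 0.1, tau = 1e-3, beta = 0.5)
  )
  expect_equal(d6$D_micro, 0.25 * 0.1^2 / (12e-3) + 0.05)
})

test_that("noise contribution and crossover lag match the error budget", {
  expect_equal(noise_contribution(0.010, 50e-6), 2)
  expect_equal(noise_contribution(0.020, 50e-6), 8)
  expect_equal(noise_contribution(0, 1e-3), 0)

  t_star <- crossover_lag(0.025, 1, R = 1 / 6, n = 1)
  expect_equal(t_star, 1.5 * 0.025^2)
  expect_equal(t_star, 9.375e-4)
  # rounds to the 0.9 ms / ~1100 Hz regime boundary
  expect_equal(round(t_star, 4), 9e-4)
  expect_equal(round(1 / t_star / 100) * 100, 1100)
  expect_equal(crossover_lag(0.025, 1, R = 0, n = 1), 0.025^2)
})

test_that("parameter validation enforces the documented ranges", {
  expect_error(model_params(7), "model_id")
  expect_error(model_params(1, R = 0.3), "R must")
  expect_error(model_params(2, alpha = 2.5), "alpha")
  expect_error(model_params(6, beta = 0), "beta")
  expect_error(eval_dapp(model_params(1, D_MACRO = 1), 0), "lag_time")
  expect_error(eval_dapp(model_params(3, tau = 1e-3), 1e-3), "requires")
})
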