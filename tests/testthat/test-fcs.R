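mk_trace <- function(intensity, dt = 1e-5) {
  structure(
    list(
      times = (seq_along(intensity) - 1) * dt,
      intensity = as.numeric(intensity), dt = dt, config = NULL
    ),
    class = "intensity_trace"
  )
}

test_that("correlator: constant and alternating traces give exact values", {
  const <- mk_trace(rep(3, 2048))
  g <- compute_acf(const)
  expect_true(all(abs(g$G - 1) < 1e-12))

  alt <- mk_trace(rep(c(0, 2), 1024))
  ga <- compute_acf(alt)
  expect_equal(ga$G[ga$lag == 0], 2)
  expect_equal(ga$G[abs(ga$lag - 1e-5) < 1e-12], 0)

  expect_error(compute_acf(mk_trace(rep(0, 2048))), "zero mean")
  expect_error(compute_acf(mk_trace(rep(1, 100))), "1024")
})

test_that("model-curve synthesis has the documented half-decay and limits", {
  cv <- make_acf_curve(0.2, 1e-3, alpha = 1, lag_grid = c(1e-4, 1e-3, 1))
  expect_equal(cv$G[2], 0.1) # G(tau_D) = G0/2 for alpha = 1
  expect_lt(cv$G[3], 1e-3) # -> 0 at long lags
  expect_error(make_acf_curve(0.1, -1), "tau_D")
})

test_that("noiseless curve refits recover (G0, tau_D, alpha) exactly", {
  for (alpha in c(0.7, 1.0)) {
    cv <- make_acf_curve(0.15, 2e-3, alpha = alpha)
    f <- fit_acf(cv, omega = 0.1, alpha_mode = "free")
    expect_equal(f$G0, 0.15, tolerance = 1e-7)
    expect_equal(f$tau_D, 2e-3, tolerance = 1e-7)
    expect_equal(f$alpha, alpha, tolerance = 1e-7)
  }
  # spot-size conversion: tau_D = 1 ms at omega = 0.1 um -> 1.803 um^2/s
  f1 <- fit_acf(make_acf_curve(0.1, 1e-3), omega = 0.1, alpha_mode = "fixed")
  expect_equal(f1$D_app, 0.01 / (8 * log(2) * 1e-3), tolerance = 1e-6)
  expect_equal(f1$D_app, 1.803, tolerance = 1e-3)
})

test_that("spot-size calibration inverts the correlation-time relation", {
  expect_equal(calibrate_omega(2.254e-3, 5), 0.25, tolerance = 1e-3)
  expect_equal(calibrate_omega(57.7e-6, 5), 0.04, tolerance = 1e-3)
  expect_equal(fcs_tau_d(0.25, 5), 2.254e-3, tolerance = 1e-3)
  expect_equal(fcs_tau_d(0.04, 5), 57.7e-6, tolerance = 1e-3)
  # quadrupling tau_D doubles omega
  expect_equal(calibrate_omega(4 * 1e-3, 5) / calibrate_omega(1e-3, 5), 2)
  # round trip is the identity
  for (om in c(0.04, 0.1, 0.25)) {
    expect_equal(calibrate_omega(fcs_tau_d(om, 5), 5), om)
  }
})

test_that("static emitters give a flat fluctuation correlation", {
  cfg <- fcs_sim_config(
    D = 0, omega = 0.1, n_emitters_mean = 200, brightness = 5,
    dt = 1e-4, duration = 4, seed = 70
  )
  g <- compute_acf(simulate_fcs_trace(cfg))
  gg <- g$G[g$lag > 0]
  early <- mean(head(gg, 10))
  late <- mean(tail(gg, 10))
  expect_lt(abs(early - late), 0.02)
})

test_that("simulated traces recover the generator D and show no spurious
           anomaly", {
  cfg <- fcs_sim_config(D = 5, omega = 0.1, duration = 8, seed = 71)
  f <- fit_acf(compute_acf(simulate_fcs_trace(cfg)), omega = 0.1)
  expect_equal(f$D_app, 5, tolerance = 0.15)
  expect_gt(f$alpha, 0.9)
  expect_lt(f$alpha, 1.1)
  # brightness does not shift the correlation time
  cfg2 <- fcs_sim_config(
    D = 5, omega = 0.1, brightness = 1, duration = 8,
    seed = 71
  )
  f2 <- fit_acf(compute_acf(simulate_fcs_trace(cfg2)), omega = 0.1)
  expect_equal(f2$tau_D, f$tau_D, tolerance = 0.15)
})

test_that("correlation amplitude scales inversely with emitter number", {
  g0 <- vapply(c(60, 120), function(ne) {
    cfg <- fcs_sim_config(
      D = 5, omega = 0.1, n_emitters_mean = ne,
      duration = 6, seed = 21
    )
    fit_acf(compute_acf(simulate_fcs_trace(cfg)), omega = 0.1)$G0
  }, numeric(1))
  expect_equal(g0[1] / g0[2], 2, tolerance = 0.2)
})

test_that("diffusion law classifies constant and hindered regimes", {
  flat <- lapply(c(0.04, 0.08, 0.16, 0.24), function(om) {
    fit_acf(make_acf_curve(0.1, fcs_tau_d(om, 2)), omega = om)
  })
  law_flat <- diffusion_law(flat)
  expect_identical(attr(law_flat, "regime"), "constant")

  pf <- model_params(5, D_MACRO = 0.078, L = 0.11, tau = 1.6e-3)
  hindered <- lapply(c(0.04, 0.08, 0.16, 0.24), function(om) {
    tau <- fcs_tau_d(om, 0.7)
    for (i in 1:80) tau <- fcs_tau_d(om, eval_dapp(pf, tau))
    fit_acf(make_acf_curve(0.1, tau), omega = om)
  })
  law_h <- diffusion_law(hindered)
  expect_identical(attr(law_h, "regime"), "hop-like")
  expect_true(all(diff(law_h$D_app) < 0))
  # omega^2 / (8 ln2 tau_D) consistency across the three numeric columns
  expect_equal(law_h$D_app, law_h$omega_sq / (8 * log(2) * law_h$tau_D))

  expect_error(diffusion_law(flat[1]), "distinct")
})
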