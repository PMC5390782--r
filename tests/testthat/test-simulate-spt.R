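test_that("config validation rejects unphysical parameters", {
  expect_error(sim_config("free", D_micro = -1), "D_micro")
  expect_error(sim_config("hop", L = 0), "L must be")
  expect_error(sim_config("free", p_cross = 1.5), "p_cross")
  expect_error(sim_config("free", t_lag = 0), "t_lag")
  expect_error(sim_config("free", exposure_fraction = 2), "exposure_fraction")
  expect_error(sim_config("free", delta_xy = -0.01), "delta_xy")
  expect_error(simulate_free(sim_config("hop")), "mode")
})

test_that("sub-step displacements follow N(0, 2 D dt) per axis", {
  cfg <- sim_config("free",
    D_micro = 1, t_lag = 1e-3, n_frames = 50,
    n_traj = 5, substeps = 50, seed = 10
  )
  sim <- simulate_free(cfg)
  steps <- as.vector(apply(sim$x, 2, diff))
  expect_gte(length(steps), 1e4)
  ks <- ks.test(steps, "pnorm", 0, sqrt(2 * 1 * 1e-3 / 50))
  expect_gt(ks$p.value, 0.01)
  # per-frame variance at substeps = 1 equals 2 D t_lag by construction
  cfg1 <- sim_config("free",
    D_micro = 1, t_lag = 1e-3, n_frames = 2000,
    n_traj = 20, substeps = 1, seed = 11
  )
  d1 <- as.vector(apply(simulate_free(cfg1)$x, 2, diff))
  expect_equal(var(d1), 2e-3, tolerance = 0.05)
})

test_that("zero diffusion leaves every position at the start", {
  cfg <- sim_config("hop",
    D_micro = 0, L = 0.1, p_cross = 0.5, n_frames = 10,
    n_traj = 4, substeps = 5, seed = 1
  )
  sim <- simulate_hop(cfg)
  expect_true(all(apply(sim$x, 2, function(v) all(v == v[1]))))
  expect_true(all(apply(sim$y, 2, function(v) all(v == v[1]))))
})

test_that("free-diffusion ensemble MSD matches 4 D n t_lag", {
  ts <- small_free_set(D = 1, n_traj = 500, n_frames = 100, seed = 12)
  cv <- ensemble_msd(ts, 10)
  se <- cv$delta_msd / sqrt(cv$n_traj)
  expect_true(all(abs(cv$msd - 4 * 1 * cv$lag_time) < 3 * se))
})

test_that("simulation output never contains NaN and conserves tracks", {
  cfg <- sim_config("hop",
    D_micro = 0.7, L = 0.11, p_cross = 0.01,
    n_frames = 50, n_traj = 25, substeps = 20, seed = 2
  )
  sim <- simulate_hop(cfg)
  expect_false(anyNA(sim$x) || anyNA(sim$y))
  ts <- apply_camera(sim)
  expect_length(ts, 25)
  expect_false(anyNA(as.data.frame(ts)$x))
})

test_that("camera model: noise floor, blur factor, and identity case", {
  # static particle + noise: mean squared frame displacement -> 4 delta^2
  delta <- 0.035
  cfg <- sim_config("immobile",
    t_lag = 1e-3, n_frames = 400, n_traj = 60,
    substeps = 1, delta_xy = delta, seed = 3
  )
  sim <- simulate_free(sim_config("free",
    D_micro = 1e-12, t_lag = 1e-3,
    n_frames = 400, n_traj = 60, substeps = 1, seed = 3
  ))
  ts <- apply_camera(sim, cfg)
  cv <- ensemble_msd(ts, 3)
  expect_equal(cv$msd[1], 4 * delta^2, tolerance = 0.03)

  # full-frame blur on free diffusion: MSD(1)/(4 t D) -> 1 - 2R = 2/3
  cfgb <- sim_config("free",
    D_micro = 1, t_lag = 1e-3, n_frames = 40,
    n_traj = 1500, substeps = 100, exposure_fraction = 1,
    delta_xy = 0, seed = 4
  )
  tsb <- apply_camera(simulate_free(cfgb))
  cvb <- ensemble_msd(tsb, 6)
  expect_equal(cvb$msd[1] / (4 * 1e-3), 2 / 3, tolerance = 0.03)
  expect_equal(cvb$msd[6] / (4 * 6e-3), 17 / 18, tolerance = 0.03)

  # exposure_fraction = 0, delta = 0 is the identity on frame samples
  simc <- simulate_free(sim_config("free",
    D_micro = 1, n_frames = 20,
    n_traj = 5, substeps = 10, seed = 5
  ))
  cfg0 <- simc$config
  cfg0$exposure_fraction <- 0
  cfg0$delta_xy <- 0
  ts0 <- apply_camera(simc, cfg0)
  idx <- (0:19) * 10 + 1
  expect_identical(ts0[[1]]$x, unname(simc$x[idx, 1]))
})

test_that("impermeable corrals plateau at L^2/3 and p_cross = 1 is free", {
  L <- 0.11
  cfg <- sim_config("confined",
    D_micro = 0.7, L = L, t_lag = 1 / 1800,
    n_frames = 120, n_traj = 250, substeps = 50, seed = 6
  )
  cv <- ensemble_msd(frame_sample(simulate_hop(cfg)), 100)
  plateau <- mean(cv$msd[cv$n >= 60])
  expect_equal(plateau, L^2 / 3, tolerance = 0.05)

  cfg1 <- sim_config("hop",
    D_micro = 0.7, L = L, p_cross = 1, t_lag = 1 / 1800,
    n_frames = 80, n_traj = 250, substeps = 20, seed = 7
  )
  cv1 <- ensemble_msd(frame_sample(simulate_hop(cfg1)), 40)
  slope <- coef(lm(msd ~ lag_time, data = cv1))[2]
  # Monte-Carlo precision of a 250-trajectory slope is a few percent
  expect_equal(unname(slope) / 4, 0.7, tolerance = 0.1)
})

test_that("partial permeability yields a long-time slope between 0 and D_micro", {
  cfg <- sim_config("hop",
    D_micro = 0.7, L = 0.11, p_cross = 0.02,
    t_lag = 1 / 1800, n_frames = 160, n_traj = 200,
    substeps = 40, seed = 8
  )
  cv <- ensemble_msd(frame_sample(simulate_hop(cfg)), 120)
  sub <- cv[cv$n >= 40, ]
  slope <- unname(coef(lm(msd ~ lag_time, data = sub))[2]) / 4
  expect_gt(slope, 0)
  expect_lt(slope, 0.7)
})

test_that("barrier undersampling triggers a warning", {
  cfg <- sim_config("hop",
    D_micro = 5, L = 0.05, p_cross = 0.1, t_lag = 1e-3,
    n_frames = 5, n_traj = 2, substeps = 1, seed = 9
  )
  expect_warning(simulate_hop(cfg), "undersampled")
})

test_that("hop calibration handles the trivial limits and is self-consistent", {
  cfg <- sim_config("hop", D_micro = 0.7, L = 0.11, substeps = 100)
  expect_equal(as.numeric(calibrate_hop(cfg, 0.7)), 1)
  expect_equal(as.numeric(calibrate_hop(cfg, 0)), 0)
  expect_error(calibrate_hop(cfg, 1.0), "unreachable")

  # calibrated permeability reproduces the target slope on a fresh seed
  p <- paper_p_cross()
  cfg2 <- sim_config("hop",
    D_micro = 0.7, L = 0.11, p_cross = p,
    t_lag = 1 / 1800, n_frames = 256, n_traj = 300,
    substeps = 100, seed = 777
  )
  cv <- ensemble_msd(frame_sample(simulate_hop(cfg2)), 128)
  sub <- cv[cv$n >= 38, ]
  slope <- unname(coef(lm(msd ~ lag_time, data = sub))[2]) / 4
  expect_equal(slope, 0.078, tolerance = 0.1)
})

test_that("study-scale ensemble is reproducible with correct composition", {
  p <- paper_p_cross()
  ens <- paper_ensemble(7)
  expect_length(ens, 493)
  labs <- attr(ens, "labels")
  expect_identical(sum(labs == "mobile"), 460L)
  expect_identical(sum(labs == "immobile"), 33L)

  again <- make_paper_ensemble(seed = 7, p_cross = p)
  expect_identical(as.data.frame(ens), as.data.frame(again))

  cls <- classify_mobility(ens)
  agree <- mean(cls$label == labs)
  expect_gte(agree, 0.9)
})
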