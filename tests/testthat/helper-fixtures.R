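# Shared, lazily built fixtures. The study-scale ensemble and its hop
# calibration are expensive, so they are computed once per test run and
# reused by every file that needs them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# calibrated barrier transmission for the study conditions
paper_p_cross <- function() {
  memo("p_cross", {
    cfg <- sim_config("hop",
      D_micro = 0.7, L = 0.11, t_lag = 1 / 1800,
      substeps = 100, delta_xy = 0.035
    )
    as.numeric(calibrate_hop(cfg, 0.078,
      tol = 0.03, n_traj = 400,
      n_frames = 256, max_iter = 18, seed = 42
    ))
  })
}

paper_ensemble <- function(seed = 7) {
  memo(paste0("ensemble_", seed), {
    make_paper_ensemble(seed = seed, p_cross = paper_p_cross())
  })
}

paper_mobile_curve <- function(seed = 7) {
  memo(paste0("mobile_curve_", seed), {
    ens <- paper_ensemble(seed)
    ensemble_msd(filter_mobility(ens, "mobile"), 90)
  })
}

paper_immobile_curve <- function(seed = 7) {
  memo(paste0("immobile_curve_", seed), {
    ens <- paper_ensemble(seed)
    ensemble_msd(filter_mobility(ens, "immobile"), 90)
  })
}

# noiseless synthetic MSD curve from a parameter set (exact forward
# evaluation of the blur/noise observation equation)
synthetic_curve <- function(params, n = 1:90, t_lag = 1 / 1800,
                            delta_msd = 1e-4) {
  y <- corrected_prediction(params, n, t_lag)
  structure(
    data.frame(
      n = as.integer(n), lag_time = n * t_lag, msd = y * 4 * n * t_lag,
      delta_msd = delta_msd, n_pairs = 1000L, n_traj = 100L
    ),
    class = c("msd_curve", "data.frame"), t_lag = t_lag
  )
}

# small free-diffusion trajectory set for cheap tests
small_free_set <- function(D = 1, n_traj = 200, n_frames = 60,
                           t_lag = 1e-3, substeps = 1, delta_xy = 0,
                           seed = 99) {
  cfg <- sim_config("free",
    D_micro = D, t_lag = t_lag, n_frames = n_frames,
    n_traj = n_traj, substeps = substeps,
    exposure_fraction = 0, delta_xy = delta_xy, seed = seed
  )
  apply_camera(simulate_free(cfg))
}
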