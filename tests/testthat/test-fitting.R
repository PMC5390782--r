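generators <- list(
  model_params(1, D_MACRO = 0.5),
  model_params(2, D_MACRO = 0.3, alpha = 0.7),
  model_params(3, L = 0.11, tau = 1.6e-3),
  model_params(4, L = 0.11, tau = 1.6e-3),
  model_params(5, D_MACRO = 0.078, L = 0.11, tau = 1.6e-3),
  model_params(6, D_MACRO = 0.078, L = 0.11, tau = 1.6e-3, beta = 0.8)
)

test_that("noiseless self-generated curves are recovered exactly for every
           model and correction variant", {
  for (gen in generators) {
    for (R in c(0, 1 / 6)) {
      for (dmode in c("zero", "free")) {
        p <- gen
        p$R <- R
        p$delta_xy <- if (dmode == "free") 0.0357 else 0
        cv <- synthetic_curve(p)
        f <- fit_msd(cv, fit_spec(p$model_id,
          R_mode = R, delta_mode = dmode,
          window = c(0.6e-3, 50e-3), weighting = "unweighted"
        ))
        expect_lt(f$rss, 1e-20)
        if (p$model_id < 6) {
          truth <- unlist(p[model_free_names(p$model_id, dmode == "free")])
          expect_equal(coef(f), truth, tolerance = 1e-7)
        } else {
          # model 6 depends on (L, tau, beta) only through beta^2 L^2 and
          # beta tau: recover the identifiable combinations instead
          e <- f$estimates
          expect_equal(e$beta^2 * e$L^2, p$beta^2 * p$L^2, tolerance = 1e-7)
          expect_equal(e$beta * e$tau, p$beta * p$tau, tolerance = 1e-7)
          expect_equal(e$D_MACRO, p$D_MACRO, tolerance = 1e-7)
          if (dmode == "free") {
            expect_equal(e$delta_xy, p$delta_xy, tolerance = 1e-7)
          }
        }
      }
    }
  }
})

test_that("weighted and unweighted fits coincide for constant dispersion", {
  p <- model_params(5,
    D_MACRO = 0.08, L = 0.1, tau = 2e-3, R = 1 / 6,
    delta_xy = 0.03
  )
  cv <- synthetic_curve(p)
  cv$msd <- cv$msd * (1 + 0.01 * sin(cv$n)) # deterministic perturbation
  # (n/delta)^2 weights vary with n even for constant delta; equality holds
  # when the weights themselves are constant
  cv$delta_msd <- cv$n * 1e-3
  fw <- fit_msd(cv, fit_spec(5,
    R_mode = 1 / 6, delta_mode = "free",
    weighting = "weighted"
  ))
  fu <- fit_msd(cv, fit_spec(5,
    R_mode = 1 / 6, delta_mode = "free",
    weighting = "unweighted"
  ))
  expect_equal(coef(fw), coef(fu), tolerance = 1e-6)
})

test_that("standard errors shrink with ensemble size", {
  fit_free <- function(n_traj, seed) {
    ts <- small_free_set(
      D = 0.5, n_traj = n_traj, n_frames = 60,
      delta_xy = 0.03, seed = seed
    )
    cv <- ensemble_msd(ts, 40)
    fit_msd(cv, fit_spec(1,
      R_mode = 0, delta_mode = "free",
      window = c(1e-3, 40e-3), weighting = "weighted"
    ))
  }
  f_small <- fit_free(100, 31)
  f_large <- fit_free(1000, 32)
  expect_lt(
    f_large$std_errors["D_MACRO"],
    f_small$std_errors["D_MACRO"]
  )
})

test_that("fitted delta on the study ensemble matches the generator noise", {
  f <- fit_msd(paper_mobile_curve(7), fit_spec(5,
    R_mode = 1 / 6,
    delta_mode = "free", window = c(0.6e-3, 50e-3), weighting = "weighted"
  ))
  expect_equal(f$estimates$delta_xy, 0.035, tolerance = 0.2)
  expect_true(f$converged)
  expect_true(all(f$p_values[c("D_MACRO", "L", "delta_xy")] < 0.001))
})

test_that("window handling: frame rounding, too few lags, weight capping", {
  p <- model_params(5,
    D_MACRO = 0.078, L = 0.11, tau = 1.6e-3, R = 1 / 6,
    delta_xy = 0.035
  )
  cv <- synthetic_curve(p)
  # 0.6 ms lower edge at 1.8 kHz includes the n = 1 lag
  f <- fit_msd(cv, fit_spec(5,
    R_mode = 1 / 6, delta_mode = "free",
    window = c(0.6e-3, 5e-3), weighting = "unweighted"
  ))
  expect_identical(min(f$data$n), 1L)
  expect_identical(max(f$data$n), 9L)

  expect_error(
    fit_msd(cv, fit_spec(5, window = c(0.6e-3, 1.2e-3))),
    "n_free"
  )

  cvz <- cv
  cvz$delta_msd[3] <- 0
  expect_warning(
    fit_msd(cvz, fit_spec(5,
      R_mode = 1 / 6, delta_mode = "free",
      weighting = "weighted"
    )),
    "capped"
  )
})

test_that("squared-displacement CDF fitting recovers r0^2 and D", {
  # single-exponential r^2 with known scale
  r2 <- local({
    set.seed(50)
    stats::rexp(4000, rate = 1 / 0.01)
  })
  f1 <- fit_sd_cdf(r2, lag_time = 1e-3, components = 1)
  expect_equal(f1$r0_sq, 0.01, tolerance = 0.05)
  expect_equal(f1$D, 0.01 / (4e-3), tolerance = 0.05)

  # 2D free diffusion at D = 1: r0^2 = 4 D t
  ts <- small_free_set(D = 1, n_traj = 400, n_frames = 3, seed = 51)
  d1 <- vapply(ts, function(tr) {
    (tr$x[2] - tr$x[1])^2 + (tr$y[2] - tr$y[1])^2
  }, numeric(1))
  f2 <- fit_sd_cdf(d1, lag_time = 1e-3, components = 1)
  expect_equal(f2$D, 1, tolerance = 0.1)

  # CDF limits and input validation
  expect_equal(1 - sum(f1$fractions * exp(-0 / f1$r0_sq)), 0)
  expect_error(fit_sd_cdf(r2[1:10], 1e-3), ">= 50")
  expect_warning(
    fit_sd_cdf(r2, 1e-3, components = 2),
    "degenerate"
  )
})
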