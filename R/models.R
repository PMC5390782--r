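#' Apparent-diffusion model parameters
#'
#' Parameter container for the six apparent-diffusion models used to fit SPT
#' MSD curves, together with the camera correction terms:
#'
#' 1. free diffusion: `D_app(t) = D_MACRO`
#' 2. anomalous diffusion: `D_app(t) = D_MACRO * t^(alpha - 1)` (with
#'    `D_MACRO` in um^2 s^-alpha and `t` in seconds)
#' 3. confined diffusion: `D_app(t) = L^2/(12 t) * (1 - exp(-t/tau))`
#' 4. confined diffusion in impermeable square corrals:
#'    `D_app(t) = L^2/(12 t) * (1 - 96/pi^4 * sum_k(odd) k^-4 *
#'    exp(-k^2 pi^2 t / (12 tau)))`
#' 5. mixed diffusion: model 3 plus a constant `D_MACRO`
#' 6. hop diffusion in permeable periodic squares: `D_MACRO + beta^2 *`
#'    the model-4 term with exponent scaled by `1/beta`
#'
#' @param model_id Integer 1-6.
#' @param D_MACRO Long-range diffusion coefficient, um^2/s (model 2:
#'   generalized coefficient, um^2 s^-alpha).
#' @param alpha Anomaly exponent in (0, 2\] (model 2).
#' @param L Compartment side, um (models 3-6).
#' @param tau Compartment relaxation time, s (models 3-6).
#' @param beta Hop-model weighting in (0, 1\] (model 6).
#' @param R Motion-blur coefficient in \[0, 1/4\] (1/6 = full-frame
#'   averaging).
#' @param delta_xy Localization error SD per coordinate, um.
#' @return A `model_params` list.
#' @export
model_params <- function(model_id, D_MACRO = NA_real_, alpha = NA_real_,
                         L = NA_real_, tau = NA_real_, beta = NA_real_,
                         R = 0, delta_xy = 0) {
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:6) stop_invalid("model_id must be 1-6")
  if (R < 0 || R > 0.25) stop_invalid("R must lie in [0, 1/4]")
  if (!is.na(alpha) && (alpha <= 0 || alpha > 2)) {
    stop_invalid("alpha must lie in (0, 2]")
  }
  if (!is.na(beta) && (beta <= 0 || beta > 1)) {
    stop_invalid("beta must lie in (0, 1]")
  }
  for (nm in c("D_MACRO", "L", "tau", "delta_xy")) {
    v <- get(nm)
    if (!is.na(v) && v < 0) stop_invalid(nm, " must be >= 0")
  }
  structure(
    list(
      model_id = model_id, D_MACRO = D_MACRO, alpha = alpha, L = L,
      tau = tau, beta = beta, R = R, delta_xy = delta_xy
    ),
    class = "model_params"
  )
}

# odd-k corral series: 96/pi^4 * sum_{k odd} k^-4 exp(-k^2 pi^2 s / 12),
# s = t / (tau * beta). Truncated when the next term falls below `rtol`
# relative to the running sum, or at k_max.
corral_series <- function(s, k_max = 199L, rtol = 1e-14) {
  acc <- numeric(length(s))
  for (k in seq(1L, k_max, by = 2L)) {
    term <- exp(-k^2 * pi^2 / 12 * s) / k^4
    acc <- acc + term
    if (max(term) < rtol * max(acc)) break
  }
  96 / pi^4 * acc
}

#' Evaluate a model's apparent diffusion coefficient
#'
#' `D_app(t) = MSD_theory(t) / (4 t)` for the chosen model (see
#' [model_params()] for the six forms). Vectorized over `lag_time`.
#'
#' @param params A [model_params()].
#' @param lag_time Lag times in seconds, all > 0.
#' @param k_max Largest odd series index for models 4 and 6.
#' @return Apparent diffusion coefficients, um^2/s.
#' @examples
#' p <- model_params(5, D_MACRO = 0.078, L = 0.110, tau = 0.0016)
#' eval_dapp(p, 1e-7) # ~ 0.708 (the t -> 0 limit D_MACRO + L^2/(12 tau))
#' @export
eval_dapp <- function(params, lag_time, k_max = 199L) {
  if (any(lag_time <= 0)) stop_invalid("lag_time must be > 0")
  t <- lag_time
  need <- function(...) {
    nms <- c(...)
    bad <- nms[vapply(nms, function(n) is.na(params[[n]]), logical(1))]
    if (length(bad)) {
      stop_invalid(
        "model ", params$model_id, " requires parameters: ",
        paste(bad, collapse = ", ")
      )
    }
  }
  switch(as.character(params$model_id),
    "1" = {
      need("D_MACRO")
      rep(params$D_MACRO, length(t))
    },
    "2" = {
      need("D_MACRO", "alpha")
      params$D_MACRO * t^(params$alpha - 1)
    },
    "3" = {
      need("L", "tau")
      params$L^2 / (12 * t) * (-expm1(-t / params$tau))
    },
    "4" = {
      need("L", "tau")
      params$L^2 / (12 * t) * (1 - corral_series(t / params$tau, k_max))
    },
    "5" = {
      need("D_MACRO", "L", "tau")
      params$D_MACRO + params$L^2 / (12 * t) * (-expm1(-t / params$tau))
    },
    "6" = {
      need("D_MACRO", "L", "tau", "beta")
      params$D_MACRO + params$beta^2 * params$L^2 / (12 * t) *
        (1 - corral_series(t / (params$tau * params$beta), k_max))
    }
  )
}

#' Predicted measured MSD/(4 n t_lag) including camera errors
#'
#' The observation equation relating the model's true apparent diffusion
#' coefficient to what a camera measures:
#' `MSD_expt(n t_lag) / (4 n t_lag) = D_app(n t_lag) * (1 - 2R/n) +
#' delta_xy^2 / (n t_lag)`.
#' The blur factor `1 - 2R/n` is strictly positive for `R <= 1/4`, `n >= 1`.
#'
#' @param params A [model_params()] (its `R` and `delta_xy` supply the
#'   correction terms).
#' @param n Integer frame lags (>= 1), vectorized.
#' @param t_lag Frame interval, s.
#' @return Predicted `MSD_expt/(4 n t_lag)` in um^2/s.
#' @export
corrected_prediction <- function(params, n, t_lag) {
  if (any(n < 1)) stop_invalid("n must be >= 1")
  blur <- 1 - 2 * params$R / n
  stopifnot(all(blur > 0))
  eval_dapp(params, n * t_lag) * blur + params$delta_xy^2 / (n * t_lag)
}

#' Derived physical quantities of a fitted model
#'
#' Computes the short-range (intra-compartment) coefficient `D_micro` from
#' the model's compartment parameters, the confinement strength
#' `S_conf = D_micro / D_MACRO`, and the confinement time
#' `tau_confinement = L^2 / (4 D_MACRO)`:
#' models 3/4 use `D_micro = L^2/(12 tau)`, model 5 adds `D_MACRO`, and
#' model 6 uses `beta^2 L^2/(12 tau) + D_MACRO`.
#'
#' @param params A [model_params()] with `model_id` in 3-6.
#' @return List with `D_micro`, `S_conf`, `tau_confinement` and logical
#'   `infinite_confinement` (`TRUE` when `D_MACRO` is zero or absent, in
#'   which case `S_conf` and `tau_confinement` are `Inf`).
#' @examples
#' derive_quantities(model_params(5, D_MACRO = 0.078, L = 0.110,
#'                                tau = 0.0016))
#' @export
derive_quantities <- function(params) {
  if (!params$model_id %in% 3:6) {
    stop_invalid("derived quantities defined for models 3-6 only")
  }
  base <- params$L^2 / (12 * params$tau)
  D_micro <- switch(as.character(params$model_id),
    "3" = base, "4" = base,
    "5" = base + params$D_MACRO,
    "6" = params$beta^2 * base + params$D_MACRO
  )
  DM <- params$D_MACRO
  inf_conf <- is.na(DM) || DM <= 0
  list(
    D_micro = D_micro,
    S_conf = if (inf_conf) Inf else D_micro / DM,
    tau_confinement = if (inf_conf) Inf else params$L^2 / (4 * DM),
    infinite_confinement = inf_conf
  )
}

#' Localization-noise contribution to the pseudo apparent diffusion
#'
#' The additive error term `delta_xy^2 / lag_time` that finite localization
#' precision contributes to `MSD/(4 n t_lag)`; it diverges as the lag goes
#' to zero and is what makes high-speed SPT so sensitive to an
#' underestimated localization error.
#'
#' @param delta_xy Localization error SD per coordinate, um.
#' @param lag_time Lag time(s), s, > 0.
#' @return Contribution in um^2/s.
#' @examples
#' noise_contribution(0.010, 50e-6) # 2 um^2/s
#' @export
noise_contribution <- function(delta_xy, lag_time) {
  if (any(lag_time <= 0)) stop_invalid("lag_time must be > 0")
  delta_xy^2 / lag_time
}

#' Lag time below which the noise term dominates the diffusion term
#'
#' Solves `delta_xy^2 / (t n (1 - 2R/n)) = D` for the frame interval `t`:
#' for shorter frame intervals the localization-noise term in the measured
#' `MSD/(4 n t_lag)` exceeds the apparent diffusion coefficient itself.
#'
#' @param delta_xy Localization error SD, um.
#' @param D Diffusion coefficient, um^2/s, > 0.
#' @param R Motion-blur coefficient.
#' @param n Frame lag (default 1).
#' @return Crossover frame interval, s.
#' @examples
#' crossover_lag(0.025, 1) # 9.375e-4 s, i.e. ~0.9 ms (~1100 Hz)
#' @export
crossover_lag <- function(delta_xy, D, R = 1 / 6, n = 1) {
  if (D <= 0) stop_invalid("D must be > 0")
  delta_xy^2 / (D * n * (1 - 2 * R / n))
}
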