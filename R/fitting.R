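#' Fit specification for corrected MSD model fitting
#'
#' Describes one fit of a corrected apparent-diffusion model to an ensemble
#' MSD curve: which model, which camera-error corrections, which time
#' window, and how data points are weighted. Fitting is performed in
#' `MSD/(4 n t_lag)` space.
#'
#' @param model_id Model 1-6 (see [model_params()]).
#' @param R_mode Motion-blur correction: `0` (none) or `1/6` (full-frame
#'   averaging). Any value in \[0, 1/4\] is accepted.
#' @param delta_mode `"zero"` (localization error fixed at 0) or `"free"`
#'   (fitted).
#' @param window Time window \[s\] of lags included in the fit; the default
#'   lower edge 0.6 ms with upper edge `t_end` = 50 ms.
#' @param weighting `"weighted"` (weights `(n / delta_msd)^2`, normalized to
#'   unit sum) or `"unweighted"`.
#' @param delta_se Whether `delta_msd` enters the weights as the
#'   across-trajectory SD (default) or as the SEM (`delta_msd/sqrt(n_traj)`);
#'   the choice cancels in the estimates but not in the reported rss scale.
#' @param restarts Number of multi-start initializations (relaxation time
#'   spread log-uniformly across the window).
#' @param start Optional named list of starting values overriding the
#'   built-in initializer.
#' @return A `fit_spec` list.
#' @export
fit_spec <- function(model_id = 5, R_mode = 1 / 6,
                     delta_mode = c("free", "zero"),
                     window = c(0.6e-3, 50e-3),
                     weighting = c("weighted", "unweighted"),
                     delta_se = c("sd", "sem"),
                     restarts = 8, start = NULL) {
  delta_mode <- match.arg(delta_mode)
  weighting <- match.arg(weighting)
  delta_se <- match.arg(delta_se)
  if (R_mode < 0 || R_mode > 0.25) stop_invalid("R_mode must lie in [0, 1/4]")
  if (length(window) != 2L || window[2L] <= window[1L]) {
    stop_invalid("window must be [t_start, t_end] with t_end > t_start")
  }
  structure(
    list(
      model_id = as.integer(model_id), R_mode = R_mode,
      delta_mode = delta_mode, window = window, weighting = weighting,
      delta_se = delta_se, restarts = as.integer(restarts), start = start
    ),
    class = "fit_spec"
  )
}

model_free_names <- function(model_id, delta_free) {
  base <- switch(as.character(model_id),
    "1" = "D_MACRO",
    "2" = c("D_MACRO", "alpha"),
    "3" = c("L", "tau"),
    "4" = c("L", "tau"),
    "5" = c("D_MACRO", "L", "tau"),
    "6" = c("D_MACRO", "L", "tau", "beta")
  )
  if (delta_free) c(base, "delta_xy") else base
}

param_bounds <- function(names) {
  lower <- c(
    D_MACRO = 0, alpha = 1e-6, L = 1e-6, tau = 1e-9,
    beta = 1e-6, delta_xy = 0
  )
  upper <- c(
    D_MACRO = Inf, alpha = 2, L = Inf, tau = Inf,
    beta = 1, delta_xy = Inf
  )
  list(lower = lower[names], upper = upper[names])
}

vec_to_params <- function(p, model_id, R) {
  do.call(model_params, c(list(model_id = model_id, R = R), as.list(p)))
}

# Profile out the linearly entering parameters. For a fixed relaxation time
# (and shape exponent), every model is linear in (D_MACRO, L^2, delta_xy^2):
#   y = D_MACRO * g0(t) * blur + L^2 * g1(t; tau) * blur + delta^2 / t
# so a weighted linear solve over a coarse tau (or alpha) grid yields
# near-optimal starting values at negligible cost.
profiled_starts <- function(free, d, spec, w, t_lag, n_keep = 2L) {
  model_id <- spec$model_id
  t <- d$lag_time
  blur <- 1 - 2 * spec$R_mode / d$n
  y <- d$y
  sw <- sqrt(w)
  delta_free <- "delta_xy" %in% free
  basis <- function(tau = NA, alpha = 1) {
    cols <- list()
    if (model_id == 2L) {
      cols$D_MACRO <- t^(alpha - 1) * blur
    } else if (model_id %in% c(1L, 5L, 6L)) {
      cols$D_MACRO <- blur
    }
    if (model_id %in% c(3L, 5L)) {
      cols$L2 <- (-expm1(-t / tau)) / (12 * t) * blur
    } else if (model_id %in% c(4L, 6L)) {
      cols$L2 <- (1 - corral_series(t / tau)) / (12 * t) * blur
    }
    if (delta_free) cols$delta2 <- 1 / t
    do.call(cbind, cols)
  }
  grid <- if (model_id == 2L) {
    data.frame(tau = NA_real_, alpha = seq(0.1, 2, length.out = 20L))
  } else if (model_id == 1L) {
    data.frame(tau = NA_real_, alpha = 1)
  } else {
    data.frame(
      tau = exp(seq(log(min(t) / 10), log(max(t) * 10), length.out = 25L)),
      alpha = 1
    )
  }
  sols <- lapply(seq_len(nrow(grid)), function(i) {
    X <- basis(grid$tau[i], grid$alpha[i])
    fit <- tryCatch(stats::lm.fit(X * sw, y * sw), error = function(e) NULL)
    if (is.null(fit)) {
      return(NULL)
    }
    list(
      rss = sum(fit$residuals^2), coefs = fit$coefficients,
      tau = grid$tau[i], alpha = grid$alpha[i]
    )
  })
  sols <- Filter(Negate(is.null), sols)
  sols <- sols[order(vapply(sols, `[[`, numeric(1), "rss"))]
  lapply(head(sols, n_keep), function(s) {
    cf <- s$coefs
    cf[is.na(cf)] <- 0
    start <- c(
      D_MACRO = max(unname(cf["D_MACRO"]), 1e-5),
      alpha = s$alpha,
      L = sqrt(max(unname(cf["L2"]), 1e-6)),
      tau = if (is.na(s$tau)) 1e-3 else s$tau,
      beta = 1,
      delta_xy = sqrt(max(unname(cf["delta2"]), 0, na.rm = TRUE))
    )
    start[free]
  })
}

# Profiled linear starts first, then heuristic log-spaced relaxation-time
# restarts for basin coverage.
fit_starts <- function(free, d, spec, w, t_lag) {
  y <- d$y
  t <- d$lag_time
  y_tail <- mean(tail(y, max(3L, length(y) %/% 5L)))
  dm0 <- max(y_tail, 1e-4)
  l2 <- 3 * mean(tail(4 * t * pmax(y - dm0, 0), max(3L, length(y) %/% 5L)))
  l0 <- sqrt(max(l2, 1e-4))
  taus <- exp(seq(log(min(t)), log(max(t)), length.out = max(2L, spec$restarts)))
  deltas <- c(0.02, 0.035, 0.005, 0.05)
  heur <- lapply(seq_along(taus), function(i) {
    s <- c(
      D_MACRO = dm0, alpha = if (i %% 2) 0.8 else 1.2, L = l0,
      tau = taus[i], beta = if (i %% 2) 0.9 else 0.5,
      delta_xy = deltas[1L + (i - 1L) %% length(deltas)]
    )
    s[free]
  })
  starts <- c(profiled_starts(free, d, spec, w, t_lag), heur)
  if (!is.null(spec$start)) {
    s0 <- starts[[1L]]
    ov <- spec$start[names(spec$start) %in% free]
    s0[names(ov)] <- unlist(ov)
    starts <- c(list(s0), starts)
  }
  starts
}

#' Fit a corrected diffusion model to an ensemble MSD curve
#'
#' Minimizes `sum_n w_n * (msd_n/(4 n t_lag) -
#' corrected_prediction(params, n, t_lag))^2` over the model's free
#' parameters by bounded Levenberg-Marquardt least squares with
#' multi-start. Weighted fits use `w_n = (n / delta_msd(n))^2` normalized to
#' unit sum (zero-dispersion lags get the largest finite weight, with a
#' warning); unweighted fits use `w_n = 1`. Lags with fewer than 3
#' contributing trajectories are dropped. Standard errors come from the
#' Jacobian-based covariance scaled by `rss / (n_points - n_free)`;
#' two-sided p-values from the t distribution with `n_points - n_free`
#' degrees of freedom, testing each estimate against zero.
#'
#' @param curve An `msd_curve` from [ensemble_msd()].
#' @param spec A [fit_spec()].
#' @return An `msd_fit` object: estimates (a [model_params()]), std_errors,
#'   t_stats, p_values, rss, n_points, n_free, derived quantities (models
#'   3-6), convergence flag, and the fitted data subset.
#' @examples
#' p <- model_params(5, D_MACRO = 0.078, L = 0.11, tau = 1.6e-3,
#'                   R = 1 / 6, delta_xy = 0.0357)
#' t_lag <- 1 / 1800
#' n <- 1:90
#' curve <- structure(
#'   data.frame(n = n, lag_time = n * t_lag,
#'              msd = corrected_prediction(p, n, t_lag) * 4 * n * t_lag,
#'              delta_msd = 1e-4, n_pairs = 100L, n_traj = 100L),
#'   class = c("msd_curve", "data.frame"), t_lag = t_lag)
#' fit <- fit_msd(curve, fit_spec(5, R_mode = 1 / 6, delta_mode = "free"))
#' coef(fit)
#' @export
fit_msd <- function(curve, spec = fit_spec()) {
  stopifnot(inherits(curve, "msd_curve"))
  t_lag <- attr(curve, "t_lag")
  # window edges in frames, rounded to the nearest lag: a 0.6 ms lower edge
  # at 1.8 kHz sampling includes the n = 1 point (0.556 ms), whose strong
  # blur factor (1 - 2R) anchors the motion-blur correction
  n_lo <- max(1L, as.integer(round(spec$window[1L] / t_lag)))
  n_hi <- as.integer(floor(spec$window[2L] / t_lag + 1e-9))
  d <- curve[curve$n >= n_lo & curve$n <= n_hi &
    curve$n_traj >= 3L, , drop = FALSE]
  if (!nrow(d)) stop_invalid("no lags inside the fit window")
  free <- model_free_names(spec$model_id, spec$delta_mode == "free")
  if (nrow(d) < length(free) + 2L) {
    stop_invalid("need at least n_free + 2 lags inside the window")
  }
  d$y <- d$msd / (4 * d$lag_time)
  if (spec$weighting == "weighted") {
    dm <- d$delta_msd
    if (spec$delta_se == "sem") dm <- dm / sqrt(d$n_traj)
    w <- (d$n / dm)^2
    if (any(!is.finite(w))) {
      cap <- max(w[is.finite(w)])
      warning("zero delta_msd at some lags; weight capped at largest finite",
        call. = FALSE
      )
      w[!is.finite(w)] <- cap
    }
    w <- w / sum(w)
  } else {
    w <- rep(1, nrow(d))
  }
  sw <- sqrt(w)
  resid_fn <- function(p) {
    pars <- vec_to_params(p, spec$model_id, spec$R_mode)
    sw * (d$y - corrected_prediction(pars, d$n, t_lag))
  }
  b <- param_bounds(free)
  best <- NULL
  for (start in fit_starts(free, d, spec, w, t_lag)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = pmax(pmin(start, b$upper), b$lower),
        lower = b$lower, upper = b$upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 400, ftol = 1e-15, ptol = 1e-15, gtol = 0
        )
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop("all optimizer starts failed", call. = FALSE)
  }
  est <- best$par
  k <- length(free)
  n_pts <- nrow(d)
  df <- n_pts - k
  rss <- best$deviance
  se <- rep(NA_real_, k)
  covm <- tryCatch(chol2inv(chol(best$hessian)) * rss / df,
    error = function(e) NULL
  )
  if (!is.null(covm)) se <- sqrt(pmax(diag(covm), 0))
  names(se) <- free
  t_stats <- est / se
  p_values <- 2 * pt(-abs(t_stats), df)
  params <- vec_to_params(est, spec$model_id, spec$R_mode)
  if (spec$delta_mode == "zero") params$delta_xy <- 0
  derived <- if (spec$model_id %in% 3:6) derive_quantities(params) else NULL
  structure(
    list(
      spec = spec, estimates = params, coefficients = est,
      std_errors = se, t_stats = t_stats, p_values = p_values,
      rss = rss, n_points = n_pts, n_free = k, df = df,
      derived = derived, converged = best$info %in% 1:4,
      weights = w, data = d, t_lag = t_lag,
      comparison_key = paste(
        spec$weighting,
        paste(signif(d$y, 15), collapse = ",")
      )
    ),
    class = "msd_fit"
  )
}

#' @export
coef.msd_fit <- function(object, ...) object$coefficients

#' @export
print.msd_fit <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<msd_fit> model %d, R = %s, delta %s, window %.2g-%.2g ms, %s\n",
    s$model_id, format(s$R_mode), s$delta_mode,
    s$window[1] * 1e3, s$window[2] * 1e3, s$weighting
  ))
  tab <- data.frame(
    estimate = x$coefficients, se = x$std_errors,
    t = x$t_stats, p = signif(x$p_values, 3)
  )
  print(tab, digits = 4)
  if (!is.null(x$derived)) {
    cat(sprintf(
      "D_micro = %.4g um^2/s, S_conf = %.3g, tau_conf = %.3g s\n",
      x$derived$D_micro, x$derived$S_conf, x$derived$tau_confinement
    ))
  }
  cat(sprintf(
    "rss = %.4g on %d points (%d free), converged: %s\n",
    x$rss, x$n_points, x$n_free, x$converged
  ))
  invisible(x)
}

#' Run the full window-by-correction fit grid for one model
#'
#' Fits `fit_msd` for every combination of time window (`t_end` values) and
#' camera-error correction variant (R = 0 or 1/6, localization error fixed
#' at zero or free), i.e. a 4 x 4 grid for the default windows, and computes
#' BIC relative likelihoods among the four correction variants within each
#' window.
#'
#' @param curve An `msd_curve`.
#' @param model_id Model 1-6.
#' @param weighting `"weighted"` or `"unweighted"`.
#' @param t_start Window lower edge, s.
#' @param t_ends Window upper edges, s.
#' @param ... Passed to [fit_spec()] (e.g. `restarts`).
#' @return A `fit_grid`: list with `fits` (keyed
#'   `tend<ms>_R<0|1/6>_d<zero|free>`) and `summary` (one row per fit with
#'   estimates, SEs, p-values, derived quantities, BIC and its relative
#'   likelihood within the window).
#' @export
fit_windows <- function(curve, model_id = 5,
                        weighting = c("weighted", "unweighted"),
                        t_start = 0.6e-3,
                        t_ends = c(5e-3, 10e-3, 25e-3, 50e-3), ...) {
  weighting <- match.arg(weighting)
  variants <- expand.grid(
    R_mode = c(0, 1 / 6), delta_mode = c("zero", "free"),
    stringsAsFactors = FALSE
  )
  fits <- list()
  rows <- list()
  for (t_end in t_ends) {
    window_fits <- list()
    for (v in seq_len(nrow(variants))) {
      spec <- fit_spec(
        model_id = model_id, R_mode = variants$R_mode[v],
        delta_mode = variants$delta_mode[v],
        window = c(t_start, t_end), weighting = weighting, ...
      )
      window_fits[[v]] <- fit_msd(curve, spec)
    }
    ics <- lapply(window_fits, information_criteria)
    rl <- relative_likelihood(ics)
    for (v in seq_len(nrow(variants))) {
      f <- window_fits[[v]]
      key <- sprintf(
        "tend%g_R%s_d%s", t_end * 1e3,
        ifelse(variants$R_mode[v] == 0, "0", "1/6"),
        variants$delta_mode[v]
      )
      fits[[key]] <- f
      est <- f$estimates
      rows[[key]] <- data.frame(
        t_end = t_end, R = variants$R_mode[v],
        delta_mode = variants$delta_mode[v], weighting = weighting,
        D_MACRO = est$D_MACRO,
        L2_over_12tau = if (!is.na(est$L)) est$L^2 / (12 * est$tau) else NA,
        L_nm = est$L * 1e3, delta_nm = est$delta_xy * 1e3,
        tau_ms = est$tau * 1e3,
        D_micro = if (!is.null(f$derived)) f$derived$D_micro else est$D_MACRO,
        bic = rl$bic[v], rl_bic = rl$rl_bic[v], rl_aic = rl$rl_aic[v],
        rss = f$rss, converged = f$converged
      )
    }
  }
  structure(
    list(
      fits = fits, summary = do.call(rbind, c(rows, make.row.names = FALSE)),
      model_id = model_id, weighting = weighting
    ),
    class = "fit_grid"
  )
}

#' @export
print.fit_grid <- function(x, ...) {
  cat(sprintf(
    "<fit_grid> model %d, %s: %d fits\n", x$model_id, x$weighting,
    length(x$fits)
  ))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Fit the cumulative distribution of squared displacements
#'
#' Fits the empirical CDF of squared displacements at one fixed lag to
#' `P(r^2) = 1 - sum_i f_i * exp(-r^2 / r0_i^2)` with `sum f_i = 1`, for one
#' or two components. For free 2D diffusion `r0^2 = 4 D t`, so each
#' component's diffusion coefficient is reported as `r0_i^2 / (4 lag_time)`.
#'
#' @param r_squared Squared displacements at the lag, um^2 (>= 50 values).
#' @param lag_time The lag these displacements span, s.
#' @param components 1 or 2.
#' @return List with `r0_sq` (um^2), `fractions`, `D` (um^2/s), `rss`, and
#'   the fitted ECDF points.
#' @export
fit_sd_cdf <- function(r_squared, lag_time, components = 1) {
  r_squared <- sort(r_squared[is.finite(r_squared)])
  if (length(r_squared) < 50L) stop_invalid("need >= 50 squared displacements")
  p_emp <- (seq_along(r_squared) - 0.5) / length(r_squared)
  r2 <- r_squared
  if (components == 1) {
    fn <- function(p) p_emp - (1 - exp(-r2 / p[1L]))
    fit <- minpack.lm::nls.lm(
      par = c(r0sq = mean(r2)), lower = 1e-12,
      fn = fn,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15)
    )
    r0 <- unname(fit$par)
    frac <- 1
  } else if (components == 2) {
    fn <- function(p) {
      f1 <- p[3L]
      p_emp - (1 - f1 * exp(-r2 / p[1L]) - (1 - f1) * exp(-r2 / p[2L]))
    }
    q <- quantile(r2, c(0.25, 0.9))
    fit <- minpack.lm::nls.lm(
      par = c(r0sq1 = unname(q[1L]), r0sq2 = unname(q[2L]), f1 = 0.5),
      lower = c(1e-12, 1e-12, 0), upper = c(Inf, Inf, 1), fn = fn,
      control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-15)
    )
    r0 <- unname(fit$par[1:2])
    frac <- unname(c(fit$par[3L], 1 - fit$par[3L]))
    if (max(r0) / min(r0) < 1.5 || min(frac) < 0.05) {
      warning("two-component fit is degenerate: r0^2 values indistinguishable",
        call. = FALSE
      )
    }
  } else {
    stop_invalid("components must be 1 or 2")
  }
  list(
    r0_sq = r0, fractions = frac, D = r0 / (4 * lag_time),
    rss = fit$deviance,
    ecdf = data.frame(r_squared = r2, p = p_emp)
  )
}
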