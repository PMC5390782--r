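#' Correlation-curve container
#'
#' Lags (seconds, strictly increasing) and normalized correlation values.
#' Two baseline conventions exist: `"raw"` (the direct normalized
#' autocorrelation `<I(t) I(t+tau)> / <I>^2`, decaying to 1) and
#' `"fluctuation"` (baseline subtracted, decaying to 0, the form the
#' diffusion model is fitted to). The convention is carried explicitly and
#' conversions are never silent.
#'
#' @param lags Lag times, s.
#' @param G Correlation values.
#' @param baseline_convention `"raw"` or `"fluctuation"`.
#' @return An `acf_curve` data frame.
#' @export
acf_curve <- function(lags, G, baseline_convention = c("raw", "fluctuation")) {
  baseline_convention <- match.arg(baseline_convention)
  if (length(lags) != length(G)) stop_invalid("lags and G lengths differ")
  if (length(lags) > 1L && any(diff(lags) <= 0)) {
    stop_invalid("lags must be strictly increasing")
  }
  structure(
    data.frame(lag = lags, G = G),
    class = c("acf_curve", "data.frame"),
    baseline_convention = baseline_convention
  )
}

#' Normalized autocorrelation of an intensity trace (multiple-tau)
#'
#' Computes the raw normalized autocorrelation
#' `G(tau) = <I(t) I(t+tau)> / <I>^2` on a quasi-logarithmic lag grid with
#' a multiple-tau scheme: the first `m` lags at full resolution, then the
#' trace is binned pairwise (factor 2) and lags `m/2+1 .. m` are evaluated
#' at each coarser level. Symmetric normalization (the two shifted segment
#' means) is used, which removes the bias from finite trace length. Lag 0
#' is included for reference but carries shot noise and is excluded from
#' fitting.
#'
#' @param trace An `intensity_trace` (>= 1024 samples).
#' @param m Lags per level (binning register size), default 16.
#' @return An `acf_curve` in raw convention (decays to 1).
#' @export
compute_acf <- function(trace, m = 16L) {
  stopifnot(inherits(trace, "intensity_trace"))
  intensity <- trace$intensity
  if (length(intensity) < 1024L) stop_invalid("trace must have >= 1024 samples")
  if (mean(intensity) <= 0) {
    stop_invalid("zero mean intensity: normalization undefined")
  }
  m <- as.integer(m)
  lags <- numeric(0)
  G <- numeric(0)
  cur <- intensity
  res <- trace$dt
  level <- 0L
  repeat {
    ks <- if (level == 0L) 0:m else (m %/% 2L + 1L):m
    n <- length(cur)
    for (k in ks) {
      if (n - k < 2L) break
      a <- cur[1:(n - k)]
      b <- cur[(1 + k):n]
      G <- c(G, mean(a * b) / (mean(a) * mean(b)))
      lags <- c(lags, k * res)
    }
    n2 <- (length(cur) %/% 2L) * 2L
    if (n2 < 4L * m) break
    cur <- (cur[seq(1L, n2, 2L)] + cur[seq(2L, n2, 2L)]) / 2
    res <- res * 2
    level <- level + 1L
  }
  o <- order(lags)
  acf_curve(lags[o], G[o], baseline_convention = "raw")
}

#' Fit the 2D anomalous-diffusion model to a correlation curve
#'
#' Least-squares fit of `G(tau) = G0 / (1 + (tau/tau_D)^alpha)` in the
#' fluctuation convention. Raw-convention input is converted first by
#' subtracting the fitted long-lag baseline (the mean of the last decade of
#' lags); lag 0, which carries uncorrelated shot noise, is excluded. The
#' apparent diffusion coefficient is derived from the supplied spot size as
#' `D_app = omega^2 / (8 ln(2) tau_D)`, with a configurable fractional
#' spot-size uncertainty (default 10%, the typical calibration precision)
#' propagated into its error.
#'
#' @param curve An `acf_curve`.
#' @param omega Observation-spot scale (FWHM), um.
#' @param alpha_mode `"free"` or `"fixed"` (alpha = 1, Brownian).
#' @param omega_frac_err Fractional uncertainty of `omega`.
#' @return An `fcs_fit` list: `G0`, `tau_D`, `alpha`, `omega`, `D_app`,
#'   `D_app_err`, `std_errors`, `converged`.
#' @export
fit_acf <- function(curve, omega, alpha_mode = c("free", "fixed"),
                    omega_frac_err = 0.1) {
  stopifnot(inherits(curve, "acf_curve"))
  alpha_mode <- match.arg(alpha_mode)
  lag <- curve$lag
  G <- curve$G
  keep <- lag > 0
  lag <- lag[keep]
  G <- G[keep]
  if (identical(attr(curve, "baseline_convention"), "raw")) {
    tail_idx <- lag >= max(lag) / 10
    G <- G - mean(G[tail_idx])
  }
  G0_0 <- max(mean(head(G, 3L)), 1e-8)
  below <- which(G <= G0_0 / 2)
  tau0 <- if (length(below)) lag[below[1L]] else median(lag)
  fn <- function(p) {
    alpha <- if (alpha_mode == "free") p[3L] else 1
    G - p[1L] / (1 + (lag / p[2L])^alpha)
  }
  par0 <- c(G0 = G0_0, tau_D = tau0)
  lower <- c(1e-12, .Machine$double.xmin)
  upper <- c(Inf, Inf)
  if (alpha_mode == "free") {
    par0 <- c(par0, alpha = 1)
    lower <- c(lower, 0.05)
    upper <- c(upper, 2)
  }
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = fn,
    control = minpack.lm::nls.lm.control(
      maxiter = 500, ftol = 1e-15, ptol = 1e-15
    )
  )
  est <- fit$par
  df <- length(G) - length(est)
  se <- rep(NA_real_, length(est))
  covm <- tryCatch(chol2inv(chol(fit$hessian)) * fit$deviance / df,
    error = function(e) NULL
  )
  if (!is.null(covm)) se <- sqrt(pmax(diag(covm), 0))
  names(se) <- names(est)
  tau_D <- unname(est["tau_D"])
  if (tau_D <= 2 * min(lag) || tau_D >= max(lag) / 2) {
    warning("fitted tau_D lies near the edge of the lag grid", call. = FALSE)
  }
  D_app <- omega^2 / (8 * log(2) * tau_D)
  se_tau <- unname(se["tau_D"])
  D_app_err <- D_app * sqrt((se_tau / tau_D)^2 + (2 * omega_frac_err)^2)
  structure(
    list(
      G0 = unname(est["G0"]), tau_D = tau_D,
      alpha = if (alpha_mode == "free") unname(est["alpha"]) else 1,
      omega = omega, D_app = D_app, D_app_err = D_app_err,
      std_errors = se, rss = fit$deviance,
      converged = fit$info %in% 1:4
    ),
    class = "fcs_fit"
  )
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<fcs_fit> omega = %.3g um: G0 = %.4g, tau_D = %.4g s, ",
      "alpha = %.3g, D_app = %.4g +/- %.2g um^2/s\n"
    ),
    x$omega, x$G0, x$tau_D, x$alpha, x$D_app, x$D_app_err
  ))
  invisible(x)
}

#' Spot-size calibration from a reference diffusion coefficient
#'
#' Inverts `D = omega^2 / (8 ln(2) tau_D)`: given the correlation time
#' measured in a calibration sample of known diffusion coefficient (e.g. a
#' fluid-phase supported lipid bilayer with D = 5 um^2/s), returns the
#' observation-spot scale `omega = sqrt(8 ln(2) D tau_D)`.
#'
#' @param tau_D_measured Measured correlation time, s.
#' @param D_reference Known diffusion coefficient, um^2/s.
#' @return Spot scale omega, um.
#' @examples
#' calibrate_omega(2.254e-3, 5) # ~0.25 um
#' @export
calibrate_omega <- function(tau_D_measured, D_reference) {
  if (tau_D_measured <= 0 || D_reference <= 0) {
    stop_invalid("tau_D_measured and D_reference must be > 0")
  }
  sqrt(8 * log(2) * D_reference * tau_D_measured)
}

#' Correlation time implied by a spot size and diffusion coefficient
#'
#' The forward relation `tau_D = omega^2 / (8 ln(2) D)`, the exact inverse
#' of [calibrate_omega()].
#'
#' @param omega Spot scale (FWHM), um.
#' @param D Diffusion coefficient, um^2/s.
#' @return Correlation time, s.
#' @export
fcs_tau_d <- function(omega, D) {
  if (omega <= 0 || D <= 0) stop_invalid("omega and D must be > 0")
  omega^2 / (8 * log(2) * D)
}

#' FCS diffusion law from fits at several spot sizes
#'
#' Collects `D_app` versus spot area (`omega^2`) and versus correlation
#' time (`tau_D`) - the two standard representations of the spot-variation
#' diffusion law - and classifies the qualitative regime from the Spearman
#' trend of `D_app` against `omega^2`: a significant negative trend
#' (`D_app` larger at smaller spots) is hop-like hindrance, a significant
#' positive trend is trapping-like, otherwise free (constant).
#'
#' @param fits List of `fcs_fit` objects at >= 2 distinct spot sizes.
#' @param sig Significance level of the trend test. The default 0.10
#'   reflects that an exact Spearman test on the typical 4-8 spot sizes has
#'   coarse p-value resolution (with 4 spots the smallest two-sided p is
#'   1/12).
#' @return A `diffusion_law` data frame (`omega`, `omega_sq`, `tau_D`,
#'   `D_app`, `D_app_err`) with attributes `regime` and `spearman`.
#' @export
diffusion_law <- function(fits, sig = 0.10) {
  if (inherits(fits, "fcs_fit")) fits <- list(fits)
  omega <- vapply(fits, `[[`, numeric(1), "omega")
  if (length(unique(omega)) < 2L) {
    stop_invalid("need fits at >= 2 distinct spot sizes")
  }
  tab <- data.frame(
    omega = omega, omega_sq = omega^2,
    tau_D = vapply(fits, `[[`, numeric(1), "tau_D"),
    D_app = vapply(fits, `[[`, numeric(1), "D_app"),
    D_app_err = vapply(fits, `[[`, numeric(1), "D_app_err")
  )
  tab <- tab[order(tab$omega), , drop = FALSE]
  ct <- suppressWarnings(
    cor.test(tab$omega_sq, tab$D_app, method = "spearman")
  )
  regime <- if (ct$p.value < sig) {
    if (unname(ct$estimate) < 0) "hop-like" else "trapping-like"
  } else {
    "constant"
  }
  structure(tab,
    class = c("diffusion_law", "data.frame"),
    regime = regime, spearman = ct
  )
}

#' @export
print.diffusion_law <- function(x, ...) {
  cat(sprintf("<diffusion_law> regime: %s\n", attr(x, "regime")))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}
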