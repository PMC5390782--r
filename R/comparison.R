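#' Error-corrected apparent diffusion coefficients from an MSD curve
#'
#' Inverts the camera observation equation per lag:
#' `D_app(n) = (msd_n / (4 n t_lag) - delta_xy^2 / (n t_lag)) / (1 - 2R/n)`.
#' The denominator is positive for all `n >= 1`, `R <= 1/4`. The per-lag
#' dispersion is propagated through the same affine transform, so the
#' corrected immobile ensemble should scatter about zero at every lag -
#' a direct, model-free validation of the correction.
#'
#' @param curve An `msd_curve`.
#' @param delta_xy Localization error SD to subtract, um (typically the
#'   value fitted on the same ensemble with the localization error free).
#' @param R Motion-blur coefficient in \[0, 1/4\].
#' @return Data frame `n`, `lag_time`, `D_app`, `dispersion`, `n_traj`.
#' @export
corrected_dapp <- function(curve, delta_xy, R = 1 / 6) {
  stopifnot(inherits(curve, "msd_curve"))
  if (delta_xy < 0) stop_invalid("delta_xy must be >= 0")
  if (R < 0 || R > 0.25) stop_invalid("R must lie in [0, 1/4]")
  blur <- 1 - 2 * R / curve$n
  data.frame(
    n = curve$n, lag_time = curve$lag_time,
    D_app = (curve$msd / (4 * curve$lag_time) -
      delta_xy^2 / curve$lag_time) / blur,
    dispersion = curve$delta_msd / (4 * curve$lag_time) / blur,
    n_traj = curve$n_traj
  )
}

#' Superimpose corrected SPT and FCS apparent diffusion coefficients
#'
#' Places error-corrected SPT points (at lag time `n t_lag`) and FCS points
#' (at correlation time `tau_D`) on one time axis and computes the mean
#' absolute relative difference between the modalities over the overlapping
#' time range, interpolating the SPT curve onto the FCS times linearly in
#' log time (both modalities sample time quasi-logarithmically). The
#' relative difference at each time is `|a - b| / ((a + b)/2)`.
#'
#' @param spt Corrected SPT table from [corrected_dapp()] (the mobile
#'   ensemble), or a named list with elements `mobile` and optionally
#'   `immobile`.
#' @param fcs A [diffusion_law()] table (or list of `fcs_fit`s).
#' @param delta_used,R_used The correction values applied to the SPT data,
#'   recorded as metadata.
#' @return A `comparison_set`: list with `spt_mobile`, `spt_immobile`
#'   (possibly NULL), `fcs`, `overlap` (data frame of matched times) and
#'   `mean_abs_rel_diff` (NA with a warning when the time ranges are
#'   disjoint).
#' @export
overlay <- function(spt, fcs, delta_used = NA_real_, R_used = NA_real_) {
  if (is.data.frame(spt)) spt <- list(mobile = spt)
  if (is.null(spt$mobile) || !nrow(spt$mobile)) {
    stop_invalid("SPT input is empty; both modalities are required")
  }
  if (!is.data.frame(fcs)) fcs <- diffusion_law(fcs)
  if (!nrow(fcs)) stop_invalid("FCS input is empty; both modalities are required")
  sp <- spt$mobile
  if (any(sp$lag_time <= 0) || any(fcs$tau_D <= 0)) {
    stop_invalid("all times must be > 0")
  }
  t_lo <- max(min(sp$lag_time), min(fcs$tau_D))
  t_hi <- min(max(sp$lag_time), max(fcs$tau_D))
  if (t_lo > t_hi) {
    warning("disjoint time ranges: overlap statistic undefined",
      call. = FALSE
    )
    overlap <- NULL
    mard <- NA_real_
  } else {
    sel <- fcs$tau_D >= t_lo & fcs$tau_D <= t_hi
    t_fcs <- fcs$tau_D[sel]
    d_fcs <- fcs$D_app[sel]
    d_spt <- approx(log(sp$lag_time), sp$D_app, xout = log(t_fcs))$y
    rel <- abs(d_spt - d_fcs) / ((d_spt + d_fcs) / 2)
    overlap <- data.frame(
      time = t_fcs, D_app_fcs = d_fcs, D_app_spt = d_spt, rel_diff = rel
    )
    mard <- mean(rel)
  }
  structure(
    list(
      spt_mobile = sp, spt_immobile = spt$immobile, fcs = fcs,
      overlap = overlap, mean_abs_rel_diff = mard,
      delta_used = delta_used, R_used = R_used
    ),
    class = "comparison_set"
  )
}

#' @export
print.comparison_set <- function(x, ...) {
  cat(sprintf(
    "<comparison_set> %d SPT mobile points, %s%d FCS points\n",
    nrow(x$spt_mobile),
    if (!is.null(x$spt_immobile)) {
      sprintf("%d SPT immobile points, ", nrow(x$spt_immobile))
    } else {
      ""
    },
    nrow(x$fcs)
  ))
  if (!is.na(x$mean_abs_rel_diff)) {
    cat(sprintf(
      "  mean |relative difference| over overlap (%d times): %.3g\n",
      nrow(x$overlap), x$mean_abs_rel_diff
    ))
  }
  invisible(x)
}

#' Plot the SPT/FCS apparent-diffusion overlay
#'
#' Log-log display of corrected SPT `D_app(n t_lag)` (mobile filled, and
#' immobile if present) with FCS `D_app(tau_D)` points, the same axes both
#' modalities are reported in (time in s, D in um^2/s).
#'
#' @param x A `comparison_set`.
#' @param ... Passed to `plot`.
#' @export
plot.comparison_set <- function(x, ...) {
  sp <- x$spt_mobile
  all_d <- c(sp$D_app, x$fcs$D_app)
  all_t <- c(sp$lag_time, x$fcs$tau_D)
  plot(sp$lag_time, pmax(sp$D_app, 1e-4),
    log = "xy", pch = 16, col = "blue3",
    xlim = range(all_t), ylim = range(pmax(all_d, 1e-4)),
    xlab = "time [s]", ylab = expression(D[app] ~ "[" * mu * m^2 ~ s^-1 * "]"),
    ...
  )
  if (!is.null(x$spt_immobile)) {
    points(x$spt_immobile$lag_time, pmax(x$spt_immobile$D_app, 1e-4),
      pch = 1, col = "grey40"
    )
  }
  points(x$fcs$tau_D, x$fcs$D_app, pch = 15, col = "black")
  legend("bottomleft",
    legend = c("SPT mobile (corrected)", "SPT immobile", "FCS"),
    pch = c(16, 1, 15), col = c("blue3", "grey40", "black"), bty = "n"
  )
  invisible(x)
}

#' @importFrom graphics legend points
NULL
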