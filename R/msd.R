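#' Time-averaged MSD of a single trajectory
#'
#' For each lag `n`, the mean over all overlapping localization pairs
#' `(i, i + n)` of the squared 2D displacement. On a deterministic straight
#' line this reduces to the ballistic `n^2` closed form; for free Brownian
#' motion it estimates `4 D n t_lag`.
#'
#' @param traj A [trajectory()] (requires contiguous frames).
#' @param max_lag Largest lag in frames; truncated with a warning if it
#'   reaches the trajectory length.
#' @return An `msd_curve` data frame with columns `n`, `lag_time`, `msd`,
#'   `delta_msd` (NA for a single trajectory), `n_pairs`, `n_traj`.
#' @examples
#' tr <- trajectory("a", 0:3, 1e-3, c(0, 1, 2, 3), rep(0, 4))
#' trajectory_msd(tr, 3)$msd # 1 4 9
#' @export
trajectory_msd <- function(traj, max_lag) {
  len <- nrow(traj)
  if (max_lag >= len) {
    warning(sprintf(
      "max_lag %d >= trajectory length %d; truncated to %d",
      max_lag, len, len - 1L
    ), call. = FALSE)
    max_lag <- len - 1L
  }
  if (max_lag < 1L) stop_invalid("trajectory too short for any lag")
  t_lag <- if (len > 1L) traj$t[2L] - traj$t[1L] else NA_real_
  m <- msd_of_xy(traj$x, traj$y, max_lag)
  new_msd_curve(
    n = seq_len(max_lag), t_lag = t_lag, msd = m$msd,
    delta_msd = rep(NA_real_, max_lag), n_pairs = m$n_pairs,
    n_traj = rep(1L, max_lag)
  )
}

msd_of_xy <- function(x, y, max_lag) {
  len <- length(x)
  msd <- numeric(max_lag)
  n_pairs <- integer(max_lag)
  for (n in seq_len(max_lag)) {
    dx <- x[(n + 1L):len] - x[1L:(len - n)]
    dy <- y[(n + 1L):len] - y[1L:(len - n)]
    msd[n] <- mean(dx * dx + dy * dy)
    n_pairs[n] <- len - n
  }
  list(msd = msd, n_pairs = n_pairs)
}

new_msd_curve <- function(n, t_lag, msd, delta_msd, n_pairs, n_traj) {
  structure(
    data.frame(
      n = as.integer(n), lag_time = n * t_lag, msd = msd,
      delta_msd = delta_msd, n_pairs = as.integer(n_pairs),
      n_traj = as.integer(n_traj)
    ),
    class = c("msd_curve", "data.frame"), t_lag = t_lag
  )
}

#' Ensemble mean MSD curve with per-lag dispersion
#'
#' Computes the time-averaged MSD of every trajectory and, per lag, the
#' unweighted mean across trajectories (`msd`), the across-trajectory
#' standard deviation (`delta_msd`), the total displacement-pair count and
#' the number of contributing trajectories. Trajectories shorter than a lag
#' simply stop contributing at that lag.
#'
#' @param trajectories A [trajectory_set()] (>= 2 tracks, common `t_lag`).
#' @param max_lag Largest lag in frames.
#' @return An `msd_curve` data frame (see [trajectory_msd()]).
#' @export
ensemble_msd <- function(trajectories, max_lag) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  if (length(trajectories) < 2L) stop_invalid("need >= 2 trajectories")
  t_lags <- vapply(
    trajectories,
    function(tr) if (nrow(tr) > 1L) tr$t[2L] - tr$t[1L] else NA_real_,
    numeric(1)
  )
  t_lags <- t_lags[!is.na(t_lags)]
  if (max(t_lags) - min(t_lags) > 1e-12 * max(t_lags)) {
    stop_invalid("incompatible ensemble: trajectories have mixed t_lag values")
  }
  t_lag <- t_lags[1L]
  max_lag <- as.integer(max_lag)
  per <- matrix(NA_real_, max_lag, length(trajectories))
  pairs <- matrix(0L, max_lag, length(trajectories))
  for (j in seq_along(trajectories)) {
    tr <- trajectories[[j]]
    ml <- min(max_lag, nrow(tr) - 1L)
    if (ml < 1L) next
    m <- msd_of_xy(tr$x, tr$y, ml)
    per[seq_len(ml), j] <- m$msd
    pairs[seq_len(ml), j] <- m$n_pairs
  }
  n_traj <- rowSums(!is.na(per))
  if (any(n_traj == 0L)) stop_invalid("no trajectory reaches max_lag")
  new_msd_curve(
    n = seq_len(max_lag), t_lag = t_lag,
    msd = rowMeans(per, na.rm = TRUE),
    delta_msd = apply(per, 1L, sd, na.rm = TRUE),
    n_pairs = rowSums(pairs), n_traj = n_traj
  )
}

#' Classify trajectories as mobile or immobile by their MSD range
#'
#' A trajectory is mobile when the range (max - min) of its time-averaged
#' MSD over the analysis window exceeds `threshold`. The default threshold
#' is 4 * (25 nm)^2 = 2.5e-3 um^2, i.e. four times the squared localization
#' precision the classification assumes. The window over which the range is
#' taken is configurable because the criterion does not by itself fix it;
#' the default matches the default fitting window (0.6-50 ms).
#'
#' @param trajectories A [trajectory_set()].
#' @param window Two-element numeric, time window \[s\] of lags to include.
#' @param threshold MSD-range threshold, um^2.
#' @return A data frame with columns `track_id`, `label`, `msd_range`,
#'   `threshold`.
#' @export
classify_mobility <- function(trajectories, window = c(0.6e-3, 50e-3),
                              threshold = 4 * 0.025^2) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  if (threshold <= 0) stop_invalid("threshold must be > 0")
  t_lag <- t_lag_of(trajectories)
  n_lo <- max(1L, as.integer(ceiling(window[1L] / t_lag - 1e-9)))
  n_hi <- as.integer(floor(window[2L] / t_lag + 1e-9))
  if (n_hi < n_lo) stop_invalid("empty analysis window")
  rng <- vapply(trajectories, function(tr) {
    ml <- min(n_hi, nrow(tr) - 1L)
    if (ml < n_lo) {
      return(NA_real_)
    }
    m <- msd_of_xy(tr$x, tr$y, ml)$msd[n_lo:ml]
    max(m) - min(m)
  }, numeric(1))
  if (all(is.na(rng))) {
    stop_invalid("invalid window: no trajectory reaches it")
  }
  data.frame(
    track_id = names(trajectories),
    label = ifelse(rng > threshold, "mobile", "immobile"),
    msd_range = rng, threshold = threshold,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Subset a trajectory set by classified (or truth) mobility
#'
#' @param trajectories A [trajectory_set()].
#' @param label `"mobile"` or `"immobile"`.
#' @param classification Optional result of [classify_mobility()]; by default
#'   the classification is computed with default settings.
#' @return A [trajectory_set()].
#' @export
filter_mobility <- function(trajectories, label = c("mobile", "immobile"),
                            classification = NULL) {
  label <- match.arg(label)
  classification <- classification %||% classify_mobility(trajectories)
  keep <- classification$track_id[classification$label == label]
  if (!length(keep)) stop_invalid("no trajectories with label '", label, "'")
  labs <- attr(trajectories, "labels")
  idx <- match(keep, names(trajectories))
  trajectory_set(unclass(trajectories)[idx], t_lag_of(trajectories),
    config = attr(trajectories, "config"),
    seed = attr(trajectories, "seed"),
    labels = if (!is.null(labs)) labs[idx]
  )
}

#' Raw pseudo apparent-diffusion view of an MSD curve
#'
#' Divides the measured MSD by `4 n t_lag` without any error correction.
#' This "pseudo-D_app" representation shows the true apparent diffusion
#' coefficient at long times but is dominated by the diverging localization
#' noise term `delta_xy^2 / (n t_lag)` as the lag goes to zero; the
#' dispersion column is the per-lag `delta_msd` transformed by the same
#' division.
#'
#' @param curve An `msd_curve`.
#' @return Data frame with columns `n`, `lag_time`, `D_pseudo` (um^2/s) and
#'   `dispersion`.
#' @seealso [corrected_dapp()] for the blur/noise-corrected counterpart.
#' @export
pseudo_dapp <- function(curve) {
  stopifnot(inherits(curve, "msd_curve"))
  denom <- 4 * curve$lag_time
  data.frame(
    n = curve$n, lag_time = curve$lag_time,
    D_pseudo = curve$msd / denom,
    dispersion = curve$delta_msd / denom
  )
}
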