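#' Write / read trajectory tables
#'
#' Trajectories are exchanged as delimited text with header
#' `track_id,frame,t,x,y` (frame 0-based, `t` in seconds, coordinates in
#' micrometers). `write_trajectories` also writes a YAML sidecar
#' (`<path>.yaml`) recording the generating configuration, seed and a
#' config hash when the set carries them. `read_trajectories` validates the
#' schema, requires strictly increasing frames and finite coordinates per
#' track (naming the offending track otherwise), and sorts by
#' `(track_id, frame)`.
#'
#' @param trajectories A [trajectory_set()].
#' @param path Output/input file path.
#' @return `write_trajectories` returns `path` invisibly;
#'   `read_trajectories` returns a [trajectory_set()].
#' @export
write_trajectories <- function(trajectories, path) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  df <- as.data.frame(trajectories)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
    path,
    row.names = FALSE, quote = FALSE
  )
  cfg <- attr(trajectories, "config")
  seed <- attr(trajectories, "seed")
  if (!is.null(cfg) || !is.null(seed)) {
    side <- list(
      config = if (!is.null(cfg)) unclass(cfg),
      seed = seed,
      config_hash = config_hash(list(cfg, seed))
    )
    yaml::write_yaml(side, paste0(path, ".yaml"))
  }
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("track_id", "frame", "t", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_invalid(
      "trajectory file missing columns: ",
      paste(missing_cols, collapse = ", ")
    )
  }
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  split_idx <- split(seq_len(nrow(df)), df$track_id)
  tracks <- lapply(split_idx, function(idx) {
    tr <- df[idx, , drop = FALSE]
    id <- tr$track_id[1L]
    if (anyNA(tr$x) || anyNA(tr$y) || anyNA(tr$t)) {
      stop_invalid("track '", id, "' contains missing coordinates")
    }
    if (any(duplicated(tr$frame))) {
      stop_invalid("track '", id, "' has duplicated frame indices")
    }
    if (nrow(tr) > 1L && any(diff(tr$frame) <= 0L)) {
      stop_invalid("track '", id, "' has non-monotone frames")
    }
    tr
  })
  t_lag <- vapply(tracks, function(tr) {
    if (nrow(tr) > 1L) (tr$t[2L] - tr$t[1L]) / (tr$frame[2L] - tr$frame[1L]) else NA_real_
  }, numeric(1))
  t_lag <- median(t_lag, na.rm = TRUE)
  tracks <- lapply(tracks, function(tr) {
    trajectory(tr$track_id[1L], tr$frame, t_lag, tr$x, tr$y)
  })
  trajectory_set(unname(tracks), t_lag)
}

#' Write / read ensemble MSD curves
#'
#' Delimited text with header `n,lag_time,msd,delta_msd,n_pairs,n_traj`
#' (`lag_time` s, `msd`/`delta_msd` um^2). Values round-trip at full
#' precision.
#'
#' @param curve An `msd_curve`.
#' @param path File path.
#' @return `write_msd_curve` returns `path` invisibly; `read_msd_curve` an
#'   `msd_curve`.
#' @export
write_msd_curve <- function(curve, path) {
  stopifnot(inherits(curve, "msd_curve"))
  write.csv(format(as.data.frame(curve), digits = 17, trim = TRUE),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_msd_curve
#' @export
read_msd_curve <- function(path) {
  df <- read.csv(path)
  required <- c("n", "lag_time", "msd", "delta_msd", "n_pairs", "n_traj")
  if (!all(required %in% names(df))) {
    stop_invalid(
      "MSD file must have columns ",
      paste(required, collapse = ",")
    )
  }
  t_lag <- df$lag_time[1L] / df$n[1L]
  new_msd_curve(df$n, t_lag, df$msd, df$delta_msd, df$n_pairs, df$n_traj)
}

#' Write a fit grid in the tabular layout of the analysis summary
#'
#' One row per (window, R, localization-error mode): long-range
#' coefficient, compartment parameters, derived short-range coefficient,
#' and BIC relative likelihood within each window.
#'
#' @param grid A `fit_grid` from [fit_windows()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_grid <- function(grid, path) {
  stopifnot(inherits(grid, "fit_grid"))
  write.csv(format(grid$summary, digits = 10, trim = TRUE),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Run the full SPT (+ optional FCS) analysis pipeline
#'
#' Executes simulate -> mobility classification -> ensemble MSD -> corrected
#' model-fit grid -> information-criterion selection -> (optional FCS
#' simulation and diffusion-law fits) -> modality overlay, writing every
#' intermediate table plus a YAML summary stamped with the seed and config
#' hash. Running twice with the same configuration and seed produces
#' byte-identical tables.
#'
#' @param config Named list (or path to a YAML file) with optional blocks:
#'   `seed`; `spt` (arguments of [make_paper_ensemble()], e.g. `n_mobile`,
#'   `n_frames`, `p_cross`); `fit` (`model_id`, `weighting`, `t_start`,
#'   `t_ends`); `fcs` (`enabled`, `omegas`, `D`, `duration`); window edges
#'   are validated before any simulation runs.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the ensemble, curves, fit grid, selection
#'   table and (if FCS ran) the comparison set; all additionally written
#'   under `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  fitcfg <- config$fit %||% list()
  t_start <- fitcfg$t_start %||% 0.6e-3
  t_ends <- fitcfg$t_ends %||% c(5e-3, 10e-3, 25e-3, 50e-3)
  sptcfg <- config$spt %||% list()
  t_lag <- sptcfg$t_lag %||% (1 / 1800)
  if (any(t_ends <= t_start)) {
    stop_invalid("invalid window: every t_end must exceed t_start")
  }
  if (t_start >= (sptcfg$n_frames %||% 200) * t_lag) {
    stop_invalid("invalid window: t_start beyond the trajectory duration")
  }
  if (all(t_ends < t_lag)) {
    stop_invalid("invalid window: all t_end below the first lag")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)

  ens <- do.call(make_paper_ensemble, c(list(seed = seed), sptcfg))
  write_trajectories(ens, file.path(out_dir, "trajectories.csv"))

  cls <- classify_mobility(ens, window = c(
    t_start,
    min(max(t_ends), (nrow(ens[[1L]]) - 1) * t_lag_of(ens))
  ))
  write.csv(cls, file.path(out_dir, "mobility.csv"), row.names = FALSE)
  mobile <- filter_mobility(ens, "mobile", cls)
  immobile <- tryCatch(filter_mobility(ens, "immobile", cls),
    error = function(e) NULL
  )

  max_lag <- min(
    as.integer(max(t_ends) / t_lag_of(ens) + 1e-9),
    nrow(ens[[1L]]) - 1L
  )
  curve_mob <- ensemble_msd(mobile, max_lag)
  write_msd_curve(curve_mob, file.path(out_dir, "msd_mobile.csv"))
  curve_imm <- if (!is.null(immobile) && length(immobile) >= 2L) {
    ensemble_msd(immobile, max_lag)
  }
  if (!is.null(curve_imm)) {
    write_msd_curve(curve_imm, file.path(out_dir, "msd_immobile.csv"))
  }

  grid <- fit_windows(
    curve_mob,
    model_id = fitcfg$model_id %||% 5,
    weighting = fitcfg$weighting %||% "weighted",
    t_start = t_start, t_ends = t_ends
  )
  write_fit_grid(grid, file.path(out_dir, "fit_grid.csv"))

  # best corrected fit in the widest window supplies the corrections
  wide <- sprintf("tend%g_R1/6_dfree", max(t_ends) * 1e3)
  best <- grid$fits[[wide]]
  delta_hat <- best$estimates$delta_xy
  spt_corr <- list(
    mobile = corrected_dapp(curve_mob, delta_hat, 1 / 6),
    immobile = if (!is.null(curve_imm)) {
      imm_spec <- fit_spec(grid$model_id,
        R_mode = 1 / 6, delta_mode = "free",
        window = c(t_start, max(t_ends)),
        weighting = grid$weighting
      )
      imm_fit <- tryCatch(fit_msd(curve_imm, imm_spec), error = function(e) NULL)
      if (!is.null(imm_fit)) {
        corrected_dapp(curve_imm, imm_fit$estimates$delta_xy, 1 / 6)
      }
    }
  )
  write.csv(spt_corr$mobile, file.path(out_dir, "dapp_mobile_corrected.csv"),
    row.names = FALSE
  )

  comparison <- NULL
  fcscfg <- config$fcs %||% list(enabled = FALSE)
  if (isTRUE(fcscfg$enabled)) {
    omegas <- fcscfg$omegas %||% c(0.04, 0.1, 0.25)
    fits <- lapply(seq_along(omegas), function(i) {
      cfg <- fcs_sim_config(
        D = fcscfg$D %||% 0.7, omega = omegas[i],
        duration = fcscfg$duration %||% 5,
        seed = seed + 7000L + i
      )
      fit_acf(compute_acf(simulate_fcs_trace(cfg)), omega = omegas[i])
    })
    law <- diffusion_law(fits)
    write.csv(as.data.frame(law), file.path(out_dir, "fcs_diffusion_law.csv"),
      row.names = FALSE
    )
    comparison <- overlay(spt_corr, law,
      delta_used = delta_hat, R_used = 1 / 6
    )
    ov <- comparison$overlap
    if (!is.null(ov)) {
      write.csv(ov, file.path(out_dir, "overlay.csv"), row.names = FALSE)
    }
  }

  summary <- list(
    seed = seed, config_hash = hash,
    package_version = as.character(utils::packageVersion("sptfcs")),
    n_tracks = length(ens),
    n_mobile = sum(cls$label == "mobile"),
    n_immobile = sum(cls$label == "immobile"),
    best_fit = list(
      window_ms = c(t_start, max(t_ends)) * 1e3,
      D_MACRO = best$estimates$D_MACRO,
      L_um = best$estimates$L, tau_s = best$estimates$tau,
      delta_xy_um = delta_hat,
      D_micro = best$derived$D_micro,
      S_conf = best$derived$S_conf,
      tau_confinement_s = best$derived$tau_confinement
    ),
    overlay_mean_abs_rel_diff = if (!is.null(comparison)) {
      comparison$mean_abs_rel_diff
    }
  )
  yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  invisible(list(
    ensemble = ens, classification = cls, msd_mobile = curve_mob,
    msd_immobile = curve_imm, grid = grid, corrected = spt_corr,
    comparison = comparison, summary = summary
  ))
}
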