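#' Trajectory containers
#'
#' A `trajectory` is a data frame with columns `track_id`, `frame` (0-based,
#' strictly increasing), `t` (seconds, `frame * t_lag`), and `x`, `y`
#' (micrometers). A `trajectory_set` is a list of trajectories sharing a
#' common frame interval, carrying that interval in the `t_lag` attribute and
#' optionally the generating configuration, seed, and ground-truth mobility
#' labels.
#'
#' @param track_id Identifier (scalar, coerced to character).
#' @param frame Integer frame indices, 0-based, strictly increasing.
#' @param t_lag Frame interval in seconds.
#' @param x,y Coordinates in micrometers.
#' @return `trajectory()` returns a `trajectory` data frame; `trajectory_set()`
#'   a `trajectory_set` list.
#' @examples
#' tr <- trajectory("a", 0:3, 1e-3, c(0, 1, 2, 3), rep(0, 4))
#' ts <- trajectory_set(list(tr), t_lag = 1e-3)
#' @export
trajectory <- function(track_id, frame, t_lag, x, y) {
  frame <- as.integer(frame)
  if (length(frame) != length(x) || length(x) != length(y)) {
    stop_invalid("trajectory coordinate/time sequences must have equal length")
  }
  if (anyNA(x) || anyNA(y)) {
    stop_invalid("trajectory '", track_id, "' has missing coordinates")
  }
  if (length(frame) > 1L && any(diff(frame) <= 0L)) {
    stop_invalid("trajectory '", track_id, "' has non-increasing frames")
  }
  structure(
    data.frame(
      track_id = as.character(track_id), frame = frame,
      t = frame * t_lag, x = x, y = y,
      stringsAsFactors = FALSE
    ),
    class = c("trajectory", "data.frame")
  )
}

#' @rdname trajectory
#' @param tracks List of `trajectory` data frames.
#' @param config Optional generating configuration ([sim_config()]).
#' @param seed Optional RNG seed recorded as metadata.
#' @param labels Optional character vector of ground-truth mobility labels
#'   (`"mobile"`/`"immobile"`), one per track.
#' @export
trajectory_set <- function(tracks, t_lag, config = NULL, seed = NULL,
                           labels = NULL) {
  if (!length(tracks)) stop_invalid("empty trajectory set")
  if (!is.null(labels) && length(labels) != length(tracks)) {
    stop_invalid("one label per track required")
  }
  ids <- vapply(tracks, function(tr) tr$track_id[1L], character(1))
  names(tracks) <- ids
  structure(tracks,
    class = "trajectory_set", t_lag = t_lag, config = config,
    seed = seed, labels = labels
  )
}

#' @export
print.trajectory_set <- function(x, ...) {
  n <- vapply(x, nrow, integer(1))
  cat(sprintf(
    "<trajectory_set> %d tracks, t_lag = %.4g s, %d-%d localizations/track\n",
    length(x), attr(x, "t_lag"), min(n), max(n)
  ))
  lb <- attr(x, "labels")
  if (!is.null(lb)) {
    cat("  truth labels:", paste(sprintf(
      "%s=%d", names(table(lb)),
      as.integer(table(lb))
    ), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.trajectory_set <- function(x, ...) {
  out <- do.call(rbind, lapply(x, as.data.frame))
  rownames(out) <- NULL
  out
}

t_lag_of <- function(ts) attr(ts, "t_lag")
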