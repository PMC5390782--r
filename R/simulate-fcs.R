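#' Configuration for the FCS intensity-trace simulator
#'
#' Emitters perform 2D Brownian motion with coefficient `D` in a periodic
#' square box; the detection profile is a Gaussian spot
#' `exp(-4 ln(2) r^2 / omega^2)` centred in the box, i.e. `omega` is the
#' profile's full width at half maximum. This is the convention under which
#' the correlation decay time of free 2D diffusion equals
#' `tau_D = omega^2 / (8 ln(2) D)` exactly, matching the spot-size/diffusion
#' relation used to convert STED-FCS correlation times to diffusion
#' coefficients.
#'
#' @param D Diffusion coefficient, um^2/s.
#' @param omega Observation-spot scale (FWHM of the detection profile), um.
#' @param n_emitters_mean Expected number of emitters in the box.
#' @param box_size Periodic box side, um (must be >= 10 * omega; the default
#'   20 * omega keeps the finite-box mode cutoff, at about
#'   box^2/(4 pi^2 D), well beyond the correlation decay so the simulated
#'   ACF tail follows the free-diffusion form).
#' @param dt Sampling interval, s (must resolve the decay:
#'   `dt < tau_D / 10`).
#' @param duration Trace duration, s.
#' @param brightness Expected counts per sample from an emitter at the spot
#'   centre.
#' @param seed RNG seed.
#' @return An `fcs_sim_config` list (with the implied `tau_D` attached).
#' @export
fcs_sim_config <- function(D = 5, omega = 0.25, n_emitters_mean = 120,
                           box_size = 20 * omega, dt = NULL,
                           duration = 10, brightness = 0.5, seed = NULL) {
  if (D < 0) stop_invalid("D must be >= 0")
  if (omega <= 0) stop_invalid("omega must be > 0")
  if (box_size < 10 * omega) stop_invalid("box_size must be >= 10 * omega")
  tau_D <- if (D > 0) omega^2 / (8 * log(2) * D) else Inf
  dt <- dt %||% (if (is.finite(tau_D)) tau_D / 12 else 1e-4)
  if (dt <= 0) stop_invalid("dt must be > 0")
  if (is.finite(tau_D) && dt >= tau_D / 10) {
    stop_invalid("dt must be < tau_D / 10 to resolve the correlation decay")
  }
  if (duration <= 0) stop_invalid("duration must be > 0")
  if (brightness <= 0) stop_invalid("brightness must be > 0")
  structure(
    list(
      D = D, omega = omega, n_emitters_mean = n_emitters_mean,
      box_size = box_size, dt = dt, duration = duration,
      brightness = brightness, seed = seed, tau_D = tau_D
    ),
    class = "fcs_sim_config"
  )
}

#' Simulate an FCS intensity trace
#'
#' The emitter count is Poisson with mean `n_emitters_mean`; each emitter
#' starts uniformly in the box and performs Brownian steps of per-axis
#' variance `2 D dt`, wrapped periodically. The expected intensity per
#' sample is `brightness * sum_i exp(-4 ln(2) r_i^2 / omega^2)` and the
#' recorded intensity is Poisson-distributed around that expectation
#' (photon shot noise).
#'
#' @param config An [fcs_sim_config()].
#' @return An `intensity_trace`: list with `times`, `intensity`, `dt`,
#'   `config`.
#' @export
simulate_fcs_trace <- function(config) {
  stopifnot(inherits(config, "fcs_sim_config"))
  n_samp <- as.integer(floor(config$duration / config$dt))
  if (n_samp < 1024L) stop_invalid("trace must contain >= 1024 samples")
  with_seed(config$seed, {
    n_em <- rpois(1L, config$n_emitters_mean)
    lambda <- numeric(n_samp)
    if (n_em > 0L && config$brightness > 0) {
      sd_step <- sqrt(2 * config$D * config$dt)
      box <- config$box_size
      half <- box / 2
      k <- 4 * log(2) / config$omega^2
      for (i in seq_len(n_em)) {
        x <- cumsum(c(runif(1L, 0, box), rnorm(n_samp - 1L, 0, sd_step))) %% box
        y <- cumsum(c(runif(1L, 0, box), rnorm(n_samp - 1L, 0, sd_step))) %% box
        lambda <- lambda + exp(-k * ((x - half)^2 + (y - half)^2))
      }
      lambda <- config$brightness * lambda
    }
    intensity <- rpois(n_samp, lambda)
  })
  structure(
    list(
      times = (seq_len(n_samp) - 1L) * config$dt,
      intensity = as.numeric(intensity), dt = config$dt, config = config
    ),
    class = "intensity_trace"
  )
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf(
    "<intensity_trace> %d samples, dt = %.3g s, mean = %.3g counts/sample\n",
    length(x$intensity), x$dt, mean(x$intensity)
  ))
  invisible(x)
}

#' Synthesize a (noisy) anomalous-diffusion correlation curve
#'
#' Returns the model curve `G(tau) = G0 / (1 + (tau / tau_D)^alpha)` on a
#' lag grid, in the fluctuation convention (decays to 0), with optional
#' i.i.d. Gaussian noise - primarily for exercising the correlation fitter.
#'
#' @param G0 Amplitude (`1/(V_eff <C>)`).
#' @param tau_D Characteristic correlation time, s.
#' @param alpha Anomaly exponent in (0, 2\] (1 = Brownian).
#' @param lag_grid Lag times, s (default: quasi-logarithmic grid spanning
#'   `tau_D/100` to `100 tau_D`).
#' @param noise_sd SD of additive Gaussian noise on G.
#' @param seed RNG seed for the noise.
#' @return An `acf_curve` (see [compute_acf()]) in fluctuation convention.
#' @export
make_acf_curve <- function(G0, tau_D, alpha = 1, lag_grid = NULL,
                           noise_sd = 0, seed = NULL) {
  if (tau_D <= 0) stop_invalid("tau_D must be > 0")
  if (alpha <= 0 || alpha > 2) stop_invalid("alpha must lie in (0, 2]")
  lag_grid <- lag_grid %||%
    exp(seq(log(tau_D / 100), log(100 * tau_D), length.out = 64L))
  G <- G0 / (1 + (lag_grid / tau_D)^alpha)
  if (noise_sd > 0) {
    G <- with_seed(seed, G + rnorm(length(G), 0, noise_sd))
  }
  acf_curve(lag_grid, G, baseline_convention = "fluctuation")
}
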