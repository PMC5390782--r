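#' Information criteria of a corrected MSD fit
#'
#' Gaussian least-squares forms: `aic = n log(rss/n) + 2k` and
#' `bic = n log(rss/n) + k log(n)` with `n` the number of fitted lags and
#' `k` the number of free parameters. The constant variance-parameter term
#' is omitted from `k` because it is identical for every model compared on
#' the same data and cancels in relative likelihoods. The rss is the
#' (weighted, where applicable) residual sum of squares of the fit, so all
#' fits entering one comparison must use the same weighting - this is
#' enforced through the comparison key.
#'
#' @param fit An `msd_fit`.
#' @return An `ic_result` list with `aic`, `bic`, the comparison key, and an
#'   `exact_fit` flag (rss = 0 yields -Inf criteria).
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "msd_fit"))
  if (!fit$converged) {
    warning("information criteria computed on a non-converged fit",
      call. = FALSE
    )
  }
  n <- fit$n_points
  k <- fit$n_free
  if (n <= k + 1L) stop_invalid("need n_points > n_free + 1")
  exact <- fit$rss <= 0
  core <- if (exact) -Inf else n * log(fit$rss / n)
  structure(
    list(
      fit_id = paste0(
        "model", fit$spec$model_id, "_R", format(fit$spec$R_mode),
        "_d", fit$spec$delta_mode
      ),
      aic = core + 2 * k, bic = core + k * log(n),
      n = n, k = k, exact_fit = exact,
      comparison_key = fit$comparison_key
    ),
    class = "ic_result"
  )
}

#' Relative likelihood of competing fits from their information criteria
#'
#' `RL_i = exp((IC_min - IC_i) / 2)` for both AIC and BIC; the best model
#' has relative likelihood exactly 1. All criteria must have been computed
#' on identical dependent-variable values (same curve, window and
#' weighting); mixing windows or weightings raises an error.
#'
#' @param ics List of `ic_result` objects (or `msd_fit`s, converted
#'   internally).
#' @return Data frame with columns `fit_id`, `aic`, `bic`, `rl_aic`,
#'   `rl_bic`.
#' @examples
#' # Delta-IC of 2 gives a relative likelihood of exp(-1) = 0.368
#' @export
relative_likelihood <- function(ics) {
  ics <- lapply(ics, function(x) {
    if (inherits(x, "msd_fit")) information_criteria(x) else x
  })
  keys <- vapply(ics, `[[`, character(1), "comparison_key")
  if (length(unique(keys)) != 1L) {
    stop_invalid(
      "incompatible comparison: information criteria were computed on ",
      "different data (window or weighting differs)"
    )
  }
  aic <- vapply(ics, `[[`, numeric(1), "aic")
  bic <- vapply(ics, `[[`, numeric(1), "bic")
  rl <- function(ic) {
    out <- exp((min(ic) - ic) / 2)
    out[ic == min(ic)] <- 1 # exact for the best model, -Inf-safe
    out
  }
  data.frame(
    fit_id = vapply(ics, `[[`, character(1), "fit_id"),
    aic = aic, bic = bic, rl_aic = rl(aic), rl_bic = rl(bic),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Compare a set of fits on the same data by AIC/BIC relative likelihood
#'
#' Convenience wrapper: computes [information_criteria()] for each fit and
#' the [relative_likelihood()] table, sorted by BIC.
#'
#' @param fits List of `msd_fit` objects fitted to the same curve, window
#'   and weighting.
#' @return Data frame as from [relative_likelihood()], ordered by `bic`.
#' @export
compare_fits <- function(fits) {
  tab <- relative_likelihood(lapply(fits, information_criteria))
  tab[order(tab$bic), , drop = FALSE]
}
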