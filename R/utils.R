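#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so that seeded simulations do not disturb the caller's
#' random stream. With `seed = NULL` the code runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_invalid <- function(...) {
  stop(structure(
    class = c("sptfcs_invalid_config", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' Cheap stable hash of an R object (hex string)
#'
#' Used to stamp output files with the generating configuration. Not
#' cryptographic; collisions only matter for human-readable provenance.
#' @noRd
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  # drop the serialization header (R version dependent)
  bytes <- bytes[-seq_len(14)]
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}
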