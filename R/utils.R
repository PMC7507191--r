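# Internal helpers shared across modules.

#' Stop with a classed condition
#'
#' @param msg message
#' @param class condition class suffix, prefixed with "tempobisect_"
#' @noRd
tb_stop <- function(msg, class) {
  stop(structure(
    class = c(paste0("tempobisect_", class), "tempobisect_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Evaluate code under a seed, restoring the caller's RNG state
#'
#' All user-facing stochastic entry points take `seed = NULL`; when a seed
#' is given the global RNG stream is left untouched so that pipelines remain
#' reproducible piecewise.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# clamp to closed interval
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# scalar finite numeric check
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
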