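#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards
# so that package functions never perturb the user's random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Round half away from zero toward positive infinity
#'
#' Commercial rounding (0.5 always rounds up) as used for top-fraction counts
#' and integer percent cells, in contrast to R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' A guard at the 9th decimal absorbs floating-point error in quotients whose
#' exact value sits on the .5 boundary (e.g. `100 * (11.7 / 7.2 - 1)`).
#'
#' @examples
#' round_half_up(78.9)  # 79
#' round_half_up(62.5)  # 63
#' @export
round_half_up <- function(x) floor(round(x + 0.5, 9))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)
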