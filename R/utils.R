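# shared helpers: classed errors, seeded RNG scopes, numerics

ms_error <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "ms_error")))
}

ms_warn <- function(class, message, ...) {
  warning(warningCondition(message, ..., class = c(class, "ms_warning")))
}

#' Evaluate code with a local, restorable RNG state
#'
#' All generators route their randomness through this helper so that a given
#' seed yields bit-identical output and the caller's RNG stream is untouched.
#' `seed = NULL` leaves the current RNG state in place.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
      if (had) assign(".Random.seed", old, envir = genv)
      else if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    }, add = TRUE)
    set.seed(as.integer(abs(seed) %% .Machine$integer.max))
  }
  code
}

#' Derive a stream-specific seed from a master seed
#'
#' Deterministic 31-bit mixing used throughout the package to give each
#' replicate, sensor or stage its own reproducible RNG stream from one master
#' seed.  `NULL` passes through.
#'
#' @param seed master integer seed (or `NULL`).
#' @param k stream index.
#' @return a 31-bit integer seed.
#' @export
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + 104729 * k) %% 2147483647L)
}

# trapezoidal integral; pracma::trapz does the arithmetic, we guard the grid
trapz_strict <- function(x, y) {
  if (length(x) < 2L || any(diff(x) <= 0)) {
    ms_error("ms_invalid_series",
             "need >= 2 strictly increasing x values for integration")
  }
  pracma::trapz(x, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_scalar <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is_scalar_number(x) && (if (strict) x > min else x >= min)
  if (!ok) {
    ms_error("ms_invalid_argument",
             sprintf("`%s` must be a finite scalar %s %s", name,
                     if (strict) ">" else ">=", format(min)))
  }
  invisible(x)
}
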