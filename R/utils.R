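#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers do not perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Decibel helpers
#'
#' `db_to_power()` and `power_to_db()` convert between decibels and linear
#' power (10 log10 convention).
#'
#' @param x numeric vector.
#' @return numeric vector.
#' @export
db_to_power <- function(x) 10^(x / 10)

#' @rdname db_to_power
#' @export
power_to_db <- function(x) 10 * log10(x)

#' Delog (linear-power) mean of decibel values
#'
#' Averages decibel values on the linear-power scale and converts back to dB,
#' the convention used for all angle-, plane- and band-averaging of target
#' strength. The result always lies between the minimum and maximum input.
#'
#' @param x numeric vector of dB values.
#' @param na.rm drop missing values.
#' @return scalar dB.
#' @export
delog_mean <- function(x, na.rm = FALSE) {
  power_to_db(mean(db_to_power(x), na.rm = na.rm))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
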