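# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# Every stochastic operation in the package funnels through this, so there is
# no hidden global state: same seed, same output.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old_seed <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old_seed, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("fracdomain_invalid_argument", "error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("fracdomain_degenerate_input", "error")))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`", name, "` must be a single finite number")
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_invalid("`", name, "` = ", format(x), " is outside the allowed range ",
                 if (open_lower) "(" else "[", lower, ", ", upper,
                 if (open_upper) ")" else "]")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
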