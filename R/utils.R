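# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a local RNG seed
#'
#' All stochastic operations in the package take an explicit `seed` argument.
#' A non-NULL seed is applied locally and the caller's RNG state is restored
#' afterwards, so no function mutates global randomness as a side effect.
#' With `seed = NULL` the current RNG stream is used (this is how nested
#' calls inside a seeded simulation draw from one reproducible stream).
#'
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_config <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integerish = FALSE, open_lower = FALSE,
                         open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config("`", name, "` must be a single finite number")
  }
  ok_lo <- if (open_lower) x > lower else x >= lower
  ok_hi <- if (open_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop_config("`", name, "` = ", format(x), " is outside the allowed range ",
                if (open_lower) "(" else "[", lower, ", ", upper,
                if (open_upper) ")" else "]")
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop_config("`", name, "` must be an integer")
  }
  x
}

# Kolmogorov-Smirnov statistic of a sample against the standard normal CDF.
ks_stat_normal <- function(x) {
  x <- sort(x)
  n <- length(x)
  u <- stats::pnorm(x)
  i <- seq_len(n)
  max(pmax(i / n - u, u - (i - 1) / n))
}
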