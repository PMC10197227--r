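#' @keywords internal
"_PACKAGE"

# Internal argument checks -----------------------------------------------

stop_pstfst <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "pstfst_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_pstfst(sprintf("`%s` must be a single finite number", name),
                "pstfst_invalid_parameter")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_pstfst(sprintf(
      "`%s` = %g is outside %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ), "pstfst_invalid_parameter")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stop_pstfst(sprintf("`%s` must be an integer >= %d", name, min),
                "pstfst_invalid_parameter")
  }
  invisible(as.integer(x))
}

#' Derive independent sub-seeds from one master seed
#'
#' Fans a single user-facing seed out to per-stage (or per-replicate) seeds by
#' a fixed arithmetic derivation, so that pipeline stages can be rerun in
#' isolation and still reproduce the full run bit-for-bit. Results stay below
#' `2^31` so they are always valid R integer seeds.
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds to derive.
#' @param stream Integer stream label separating independent uses of the same
#'   master seed (e.g. one stream per pipeline stage).
#' @return Integer vector of `n` seeds.
#' @export
derive_seeds <- function(seed, n, stream = 0L) {
  check_count(seed, "seed", min = 0L)
  check_count(n, "n")
  check_count(stream, "stream", min = 0L)
  # multiplicative hash mod a Mersenne prime keeps seeds in 32-bit range
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (s * 48271 + 11 * (stream + 1) + i) %% m
    out[i] <- s
  }
  as.integer(out)
}

# quantile bounds of an equal-tailed interval with total mass `mass`
interval_probs <- function(mass) {
  c((1 - mass) / 2, 1 - (1 - mass) / 2)
}
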