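# Internal validation and seeding helpers.

# Stop with a classed condition so callers can test failures precisely.
stop_invalid <- function(msg, ..., class = "asdkit_invalid") {
  abort(msg, class = c(class, "asdkit_error"), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop_invalid(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ))
  }
  invisible(x)
}

check_positive_vector <- function(x, name) {
  if (length(x) == 0L || !is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_invalid(sprintf("`%s` must be a non-empty vector of positive finite numbers", name))
  }
  invisible(x)
}

check_increasing <- function(x, name) {
  if (any(diff(x) <= 0)) {
    stop_invalid(sprintf("`%s` must be strictly increasing", name))
  }
  invisible(x)
}

check_fractions <- function(x, name, tol = 1e-8) {
  check_positive_vector(x, name)
  if (abs(sum(x) - 1) > tol) {
    stop_invalid(sprintf("`%s` must sum to 1 (got %.10f)", name, sum(x)))
  }
  invisible(x)
}

#' Derive a stage-specific seed from a global seed
#'
#' A single global seed fans out to sub-stages keyed by stage name (a plain
#' polynomial string hash folded into `[0, 2^31 - 2]`), so adding stages
#' never perturbs the random streams of existing ones.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (any string).
#' @return A deterministic integer seed.
#' @examples
#' derive_seed(42, "recovery")
#' @export
derive_seed <- function(seed, stage) {
  check_number(seed, "seed")
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147480009
  as.integer((as.numeric(seed) %% 2147480009 + h) %% 2147480009)
}

# Evaluate `expr` under a local RNG seed without touching the caller's stream.
with_seed_ <- function(seed, expr) {
  withr::with_seed(seed, expr)
}
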