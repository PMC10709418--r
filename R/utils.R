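## Internal helpers shared across modules.

#' Round a percentage the way category summaries are printed
#'
#' Values of 10 or more round to the nearest integer, values below 10 keep
#' one decimal. Half-values round away from zero so printed tables never
#' depend on the platform's banker's rounding.
#'
#' @param pct numeric vector of percentages (0-100 scale).
#' @return numeric vector of printed-precision percentages.
#' @export
round_pct <- function(pct) {
  stopifnot(is.numeric(pct))
  ifelse(pct >= 10,
         floor(pct + 0.5),
         floor(pct * 10 + 0.5) / 10)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a scalar probability; errors name the offending field.
check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("configuration error: '%s' must be a probability in [0, 1]",
                 field), call. = FALSE)
  }
  invisible(x)
}

check_positive <- function(x, field, integer = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0
  if (ok && integer) ok <- x == as.integer(x)
  if (!ok) {
    stop(sprintf("configuration error: '%s' must be a positive %s",
                 field, if (integer) "integer" else "number"), call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop(sprintf("configuration error: '%s' must be non-negative", field),
         call. = FALSE)
  }
  invisible(x)
}

#' Nearest-rank empirical quantile
#'
#' The nearest-rank definition keeps integer-event semantics: the returned
#' threshold is always an observed value. `q = 0` returns the minimum.
#'
#' @param x numeric vector (non-empty).
#' @param q quantile in `[0, 1]`.
#' @keywords internal
nearest_rank_quantile <- function(x, q) {
  stopifnot(length(x) > 0, q >= 0, q <= 1)
  xs <- sort(x)
  k <- max(1L, as.integer(ceiling(q * length(xs))))
  xs[k]
}
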