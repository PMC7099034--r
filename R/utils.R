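`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

assert_scalar_num <- function(x, field, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(field, "must be a finite numeric scalar")
  if (strict_lower && x <= lower)
    stop_config(field, sprintf("must be > %g", lower))
  if (!strict_lower && x < lower)
    stop_config(field, sprintf("must be >= %g", lower))
  if (x > upper)
    stop_config(field, sprintf("must be <= %g", upper))
  invisible(x)
}

assert_prob <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_config(field, "must lie in [0, 1]")
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @importFrom stats median
median_filter_1d <- function(x, window = 3L) {
  n <- length(x)
  if (n == 0L || window <= 1L) return(x)
  half <- window %/% 2L
  out <- x
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- median(x[lo:hi], na.rm = TRUE)
  }
  out
}

# first index at which `cond` holds for `sustain` consecutive entries
first_sustained <- function(cond, sustain = 2L, start = 1L) {
  cond[is.na(cond)] <- FALSE
  n <- length(cond)
  if (start > n) return(NA_integer_)
  run <- 0L
  for (i in start:n) {
    run <- if (cond[i]) run + 1L else 0L
    if (run >= sustain) return(i - sustain + 1L)
  }
  NA_integer_
}

# (Z, Y, X) volume of one frame/channel, robust to singleton dimensions
get_vol <- function(stack, t, ch) {
  d <- dim(stack$data)
  array(stack$data[t, ch, , , ], dim = d[3:5])
}
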