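#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. All random stages take an explicit
# seed and restore the caller's RNG state (withr::with_seed), so no function
# here reads or mutates global random state implicitly.

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`%s` must be a single finite number", name)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_invalid("`%s` = %g is outside its valid range", name, x)
  }
  invisible(x)
}

# Derive a stage seed from a master seed; keeps results < 2^31 so they are
# representable as R integers.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 12007L) %% 2147483629)
}

with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Centered boxcar mean with shrinking windows at the edges (no NA padding).
rolling_mean_centered <- function(x, width) {
  n <- length(x)
  if (width <= 1L || n < 2L) return(x)
  half <- floor(width / 2)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Rolling sum over `width` rows of a matrix. mode "past": rows
# max(1, t-width+1) .. t (causal, inclusive of t). mode "centered":
# width rows centered on t, truncated at the edges.
rolling_sum <- function(x, width, mode = c("centered", "past")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  n <- nrow(x)
  if (width <= 1L || n < 2L) return(x)
  cs <- rbind(0, apply(x, 2L, cumsum))
  if (mode == "past") {
    lo <- pmax(seq_len(n) - width, 0L)
    hi <- seq_len(n)
  } else {
    back <- floor((width - 1) / 2)
    lo <- pmax(seq_len(n) - back - 1L, 0L)
    hi <- pmin(seq_len(n) + (width - 1L - back), n)
  }
  cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
}

row_max_values <- function(x) {
  # rowwise max of a numeric matrix that may contain -Inf
  idx <- max.col(x, ties.method = "first")
  x[cbind(seq_len(nrow(x)), idx)]
}
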