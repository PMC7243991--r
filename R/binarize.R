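#' Binary activity raster container
#'
#' Neuron x frame matrix of active (1) / inactive (0) states produced by one
#' of the binarization methods, together with the settings used.
#'
#' @param states neuron x frame 0/1 matrix.
#' @param sampling_rate frame rate in Hz.
#' @param method one of `"rise"`, `"threshold"`, `"deconvolved"`.
#' @param parameters named list recording the settings used.
#' @return An object of class `binary_raster`.
#' @export
binary_raster <- function(states, sampling_rate, method, parameters = list()) {
  states <- as.matrix(states)
  if (!all(states %in% c(0, 1))) stop_invalid("raster states must be 0/1")
  storage.mode(states) <- "integer"
  check_scalar_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  structure(list(states = states, sampling_rate = sampling_rate,
                 method = method, parameters = parameters),
            class = "binary_raster")
}

#' @export
print.binary_raster <- function(x, ...) {
  cat(sprintf("<binary_raster> %d neurons x %d frames (%s), %.2f%% active\n",
              nrow(x$states), ncol(x$states), x$method,
              100 * mean(x$states)))
  invisible(x)
}

# Zero-phase low-pass with an order-4 Butterworth magnitude response,
# applied in the Fourier domain on a mirror-padded signal. Unit gain at DC,
# so affine transforms of the input commute with the filter.
lowpass_zero_phase <- function(x, cutoff_hz, sampling_rate, order = 4) {
  n <- length(x)
  pad <- min(n - 1L, max(2L, ceiling(3 * sampling_rate / cutoff_hz)))
  xp <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  np <- length(xp)
  f <- (seq_len(np) - 1L) * sampling_rate / np
  f <- pmin(f, sampling_rate - f)
  H <- 1 / sqrt(1 + (f / cutoff_hz)^(2 * order))
  y <- Re(stats::fft(stats::fft(xp) * H, inverse = TRUE)) / np
  y[(pad + 1L):(pad + n)]
}

binarize_one_rise <- function(x, z_threshold, cutoff_hz, sampling_rate) {
  if (stats::sd(x) == 0) return(NULL)
  xf <- if (is.null(cutoff_hz)) x else {
    lowpass_zero_phase(x, cutoff_hz, sampling_rate)
  }
  s <- stats::sd(xf)
  if (s == 0) return(NULL)
  z <- (xf - mean(xf)) / s
  rising <- c(FALSE, diff(z) > 0)
  as.integer(z > z_threshold & rising)
}

#' Binarize traces by the transient-rise criterion
#'
#' The package's primary binarization: each trace is low-pass filtered
#' (zero-phase, order-4 Butterworth-type magnitude response) to remove frame
#' noise, z-scored over the whole recording, and frame `t` is marked active
#' iff the z-scored signal exceeds `z_threshold` standard deviations AND its
#' first difference `z(t) - z(t-1)` is positive, i.e. the transient is
#' rising. Rise periods carry most action potentials, which is why only they
#' are labeled active. Frame 1 is always inactive (the derivative is
#' undefined there).
#'
#' Zero-variance (dead) traces produce an all-inactive row plus a warning
#' rather than an error, so dead ROIs do not abort batch runs.
#'
#' @param traces a [calcium_traces()].
#' @param z_threshold activity threshold in SD units (default 2).
#' @param lowpass_cutoff_hz low-pass cutoff in Hz (default 2); must lie
#'   below the Nyquist frequency. `NULL` disables filtering.
#' @return A [binary_raster()] with `method = "rise"`.
#' @export
binarize_rise <- function(traces, z_threshold = 2, lowpass_cutoff_hz = 2) {
  stopifnot(inherits(traces, "calcium_traces"))
  if (!is.null(lowpass_cutoff_hz)) {
    check_scalar_number(lowpass_cutoff_hz, "lowpass_cutoff_hz",
                        lower = 0, upper = traces$sampling_rate / 2,
                        strict_lower = TRUE, strict_upper = TRUE)
  }
  states <- matrix(0L, nrow(traces$values), ncol(traces$values))
  dead <- 0L
  for (k in seq_len(nrow(states))) {
    row <- binarize_one_rise(traces$values[k, ], z_threshold,
                             lowpass_cutoff_hz, traces$sampling_rate)
    if (is.null(row)) dead <- dead + 1L else states[k, ] <- row
  }
  if (dead > 0L) {
    warning(sprintf("%d zero-variance trace(s) binarized as all-inactive", dead),
            call. = FALSE)
  }
  binary_raster(states, traces$sampling_rate, "rise",
                list(z_threshold = z_threshold,
                     lowpass_cutoff_hz = lowpass_cutoff_hz))
}

#' Binarize traces by a simple z-score threshold
#'
#' Comparison method: a frame is active iff the unfiltered, z-scored trace
#' exceeds `z_threshold` SD — no derivative criterion, so the active set is
#' a superset of the rise criterion applied to the same (unfiltered) trace.
#'
#' @inheritParams binarize_rise
#' @return A [binary_raster()] with `method = "threshold"`.
#' @export
binarize_threshold <- function(traces, z_threshold = 2) {
  stopifnot(inherits(traces, "calcium_traces"))
  states <- matrix(0L, nrow(traces$values), ncol(traces$values))
  dead <- 0L
  for (k in seq_len(nrow(states))) {
    x <- traces$values[k, ]
    s <- stats::sd(x)
    if (s == 0) dead <- dead + 1L else {
      states[k, ] <- as.integer((x - mean(x)) / s > z_threshold)
    }
  }
  if (dead > 0L) {
    warning(sprintf("%d zero-variance trace(s) binarized as all-inactive", dead),
            call. = FALSE)
  }
  binary_raster(states, traces$sampling_rate, "threshold",
                list(z_threshold = z_threshold))
}

#' Binarize a deconvolved activity matrix
#'
#' Comparison method for pipelines that run spike deconvolution upstream
#' (e.g. a first-order autoregressive model): any strictly positive
#' deconvolved value marks an active frame. Deconvolution itself is out of
#' scope; this adapter only consumes its output.
#'
#' @param deconvolved neuron x frame matrix of non-negative deconvolved
#'   activity values.
#' @param sampling_rate frame rate in Hz.
#' @return A [binary_raster()] with `method = "deconvolved"`.
#' @export
binarize_from_deconvolved <- function(deconvolved, sampling_rate = 30) {
  deconvolved <- as.matrix(deconvolved)
  if (!all(is.finite(deconvolved))) stop_invalid("deconvolved values must be finite")
  if (any(deconvolved < 0)) {
    stop_invalid("deconvolved activity must be non-negative")
  }
  binary_raster((deconvolved > 0) * 1L, sampling_rate, "deconvolved")
}
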