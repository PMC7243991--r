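#' Behavioral tracking container
#'
#' Bundles per-sample timestamps (seconds) with 1D or 2D position (cm) and
#' the arena bounds. All generators and readers in the package produce this
#' class; downstream discretization consumes it.
#'
#' @param timestamps numeric vector, strictly increasing, seconds.
#' @param position numeric vector (1D) or matrix/data.frame with one row per
#'   timestamp and one column per spatial coordinate (cm).
#' @param arena_bounds numeric vector of upper bounds per coordinate (cm);
#'   the lower bound is 0.
#' @return An object of class `behavior_track` with elements `timestamps`,
#'   `position` (matrix, one column per coordinate), `arena_bounds`, `ndim`.
#' @export
behavior_track <- function(timestamps, position, arena_bounds) {
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) < 1L) stop_invalid("track needs at least one sample")
  if (any(diff(timestamps) <= 0)) {
    stop_invalid("track timestamps must be strictly increasing")
  }
  position <- as.matrix(position)
  storage.mode(position) <- "double"
  dimnames(position) <- NULL
  if (nrow(position) != length(timestamps)) {
    stop_invalid("one position record per timestamp required (%d vs %d)",
                 nrow(position), length(timestamps))
  }
  ndim <- ncol(position)
  if (!ndim %in% c(1L, 2L)) stop_invalid("position must have 1 or 2 coordinates")
  arena_bounds <- as.numeric(arena_bounds)
  if (length(arena_bounds) != ndim || any(arena_bounds <= 0)) {
    stop_invalid("arena_bounds must give one positive upper bound per coordinate")
  }
  ok <- is.finite(position)
  inside <- position[ok] >= -1e-9 &
    position[ok] <= rep(arena_bounds, each = nrow(position))[ok]
  if (!all(inside)) stop_invalid("positions fall outside arena_bounds")
  structure(list(timestamps = timestamps, position = position,
                 arena_bounds = arena_bounds, ndim = ndim),
            class = "behavior_track")
}

#' @export
print.behavior_track <- function(x, ...) {
  cat(sprintf("<behavior_track> %dD, %d samples, %.1f s, arena %s cm\n",
              x$ndim, length(x$timestamps), diff(range(x$timestamps)),
              paste(signif(x$arena_bounds, 3), collapse = " x ")))
  invisible(x)
}

#' Calcium fluorescence traces container
#'
#' @param values neuron x frame numeric matrix of fluorescence (arbitrary
#'   units); all values must be finite.
#' @param sampling_rate imaging frame rate in Hz (> 0).
#' @param timestamps optional per-frame times (seconds); defaults to a
#'   regular clock starting at 0.
#' @return An object of class `calcium_traces`.
#' @export
calcium_traces <- function(values, sampling_rate, timestamps = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop_invalid("trace values must all be finite")
  check_scalar_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  if (is.null(timestamps)) {
    timestamps <- (seq_len(ncol(values)) - 1L) / sampling_rate
  }
  if (length(timestamps) != ncol(values)) {
    stop_invalid("frame count (%d) must equal timestamp count (%d)",
                 ncol(values), length(timestamps))
  }
  structure(list(values = values, sampling_rate = sampling_rate,
                 timestamps = as.numeric(timestamps)),
            class = "calcium_traces")
}

#' @export
print.calcium_traces <- function(x, ...) {
  cat(sprintf("<calcium_traces> %d neurons x %d frames @ %.3g Hz\n",
              nrow(x$values), ncol(x$values), x$sampling_rate))
  invisible(x)
}

#' Simulate back-and-forth running on a linear track
#'
#' Generates a 1D trajectory on the imaging frame clock: ballistic runs at
#' `mean_speed_cms` with Gaussian speed jitter, direction reversal at the
#' track ends, and (optionally) exponential-duration immobility pauses at
#' the reward ends — the structure of a water-rewarded linear-track task.
#'
#' @param duration_s session length in seconds (> 0).
#' @param sampling_rate_hz frame rate in Hz (> 0); behavior is generated
#'   directly on the frame clock.
#' @param track_length_cm track length in cm (> 0).
#' @param mean_speed_cms mean running speed, cm/s.
#' @param pause_prob probability of pausing on each arrival at a track end.
#' @param mean_pause_s mean duration of an immobility pause, seconds.
#' @param speed_jitter per-frame multiplicative speed SD (fraction of mean).
#' @param seed integer seed; fixed seed gives a bit-identical trajectory.
#' @return A [behavior_track()].
#' @export
simulate_behavior_1d <- function(duration_s, sampling_rate_hz = 30,
                                 track_length_cm = 100, mean_speed_cms = 20,
                                 pause_prob = 0.5, mean_pause_s = 2,
                                 speed_jitter = 0.1, seed = NULL) {
  check_scalar_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_scalar_number(sampling_rate_hz, "sampling_rate_hz", lower = 0, strict_lower = TRUE)
  check_scalar_number(track_length_cm, "track_length_cm", lower = 0, strict_lower = TRUE)
  check_scalar_number(mean_speed_cms, "mean_speed_cms", lower = 0)
  check_scalar_number(pause_prob, "pause_prob", lower = 0, upper = 1)
  n <- round(duration_s * sampling_rate_hz)
  dt <- 1 / sampling_rate_hz
  pos <- with_seed_(seed, {
    jit <- pmax(0, 1 + stats::rnorm(n, 0, speed_jitter))
    p <- numeric(n)
    x <- 0
    dir <- 1
    pause_left <- 0L
    for (t in seq_len(n)) {
      if (pause_left > 0L) {
        pause_left <- pause_left - 1L
      } else {
        x <- x + dir * mean_speed_cms * jit[t] * dt
        if (x >= track_length_cm) {
          x <- track_length_cm
          dir <- -1
          if (stats::runif(1) < pause_prob) {
            pause_left <- as.integer(round(stats::rexp(1, 1 / mean_pause_s) *
                                             sampling_rate_hz))
          }
        } else if (x <= 0) {
          x <- 0
          dir <- 1
          if (stats::runif(1) < pause_prob) {
            pause_left <- as.integer(round(stats::rexp(1, 1 / mean_pause_s) *
                                             sampling_rate_hz))
          }
        }
      }
      p[t] <- x
    }
    p
  })
  behavior_track((seq_len(n) - 1L) * dt, pos, track_length_cm)
}

#' Simulate open-field exploration
#'
#' A persistent (correlated) random walk: the heading diffuses with
#' per-frame SD `turn_sd_rad` while speed fluctuates around
#' `mean_speed_cms`; walls reflect. This produces the smooth, curved
#' paths typical of a mouse exploring an open field, with inhomogeneous
#' but eventually complete arena coverage.
#'
#' @inheritParams simulate_behavior_1d
#' @param arena_cm width and height of the arena (cm); a scalar is used for
#'   both sides.
#' @param turn_sd_rad per-frame heading diffusion SD in radians.
#' @return A [behavior_track()] with 2D positions.
#' @export
simulate_behavior_2d <- function(duration_s, sampling_rate_hz = 30,
                                 arena_cm = c(45, 45), mean_speed_cms = 20,
                                 turn_sd_rad = 0.25, speed_jitter = 0.1,
                                 seed = NULL) {
  check_scalar_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_scalar_number(sampling_rate_hz, "sampling_rate_hz", lower = 0, strict_lower = TRUE)
  if (length(arena_cm) == 1L) arena_cm <- rep(arena_cm, 2L)
  if (any(arena_cm <= 0)) stop_invalid("arena_cm must be positive")
  n <- round(duration_s * sampling_rate_hz)
  dt <- 1 / sampling_rate_hz
  pos <- with_seed_(seed, {
    heading <- cumsum(c(stats::runif(1, 0, 2 * pi),
                        stats::rnorm(n - 1, 0, turn_sd_rad)))
    step <- pmax(0, mean_speed_cms * (1 + stats::rnorm(n, 0, speed_jitter))) * dt
    raw_x <- arena_cm[1] / 2 + cumsum(step * cos(heading))
    raw_y <- arena_cm[2] / 2 + cumsum(step * sin(heading))
    # fold the unconstrained path into the box: exact specular reflection
    fold <- function(x, L) L - abs(x %% (2 * L) - L)
    cbind(fold(raw_x, arena_cm[1]), fold(raw_y, arena_cm[2]))
  })
  behavior_track((seq_len(n) - 1L) * dt, pos, arena_cm)
}

#' Simulate Gaussian place cells on a trajectory
#'
#' Each cell emits binary events per frame with probability
#' `baseline + (p_max - baseline) * exp(-d^2 / (2 * field_width^2))`, where
#' `d` is the distance from the current position to the cell's field
#' center. Field centers tile the arena evenly with uniform jitter of one
#' spatial bin, so a tiled population covers the whole arena. A fraction of
#' cells can be made direction-selective (1D tracks only): they use the
#' place-field rate only when the animal travels in their preferred
#' direction and fire at `baseline` otherwise.
#'
#' @param track a [behavior_track()] on the frame clock.
#' @param n_cells number of cells to simulate.
#' @param field_width_cm Gaussian field SD in cm (recycled per cell).
#' @param p_max peak per-frame emission probability in (0, 1] (recycled).
#' @param baseline out-of-field per-frame probability, `< p_max` (recycled).
#' @param frac_directional fraction of cells that are direction selective.
#' @param jitter_cm half-width of the uniform center jitter (one bin).
#' @param seed integer seed.
#' @return A list with `spikes` (n_cells x frame 0/1 matrix) and
#'   `ground_truth` (data.frame: cell, center coordinates, field_width,
#'   p_max, baseline, direction_pref).
#' @export
simulate_place_cells <- function(track, n_cells, field_width_cm = 5,
                                 p_max = 0.1, baseline = 0.01,
                                 frac_directional = 0, jitter_cm = 3,
                                 seed = NULL) {
  stopifnot(inherits(track, "behavior_track"))
  check_scalar_number(frac_directional, "frac_directional", lower = 0, upper = 1)
  p_max <- rep_len(as.numeric(p_max), n_cells)
  baseline <- rep_len(as.numeric(baseline), n_cells)
  field_width_cm <- rep_len(as.numeric(field_width_cm), n_cells)
  if (any(p_max <= 0 | p_max > 1)) stop_invalid("p_max must lie in (0, 1]")
  if (any(baseline < 0) || any(p_max <= baseline)) {
    stop_invalid("baseline must be non-negative and strictly below p_max")
  }
  if (track$ndim == 2L && frac_directional > 0) {
    stop_invalid("direction-selective cells are defined for 1D tracks only")
  }
  n_frames <- nrow(track$position)
  with_seed_(seed, {
    if (track$ndim == 1L) {
      L <- track$arena_bounds[1]
      centers <- cbind(pmin(pmax(
        L * (seq_len(n_cells) - 0.5) / n_cells +
          stats::runif(n_cells, -jitter_cm, jitter_cm), 0), L))
    } else {
      nx <- ceiling(sqrt(n_cells))
      ny <- ceiling(n_cells / nx)
      gx <- track$arena_bounds[1] * ((seq_len(nx) - 0.5) / nx)
      gy <- track$arena_bounds[2] * ((seq_len(ny) - 0.5) / ny)
      grid <- expand.grid(x = gx, y = gy)[seq_len(n_cells), ]
      centers <- cbind(
        pmin(pmax(grid$x + stats::runif(n_cells, -jitter_cm, jitter_cm), 0),
             track$arena_bounds[1]),
        pmin(pmax(grid$y + stats::runif(n_cells, -jitter_cm, jitter_cm), 0),
             track$arena_bounds[2]))
    }
    n_dir <- round(frac_directional * n_cells)
    dir_pref <- rep("none", n_cells)
    if (n_dir > 0) {
      dir_cells <- sample.int(n_cells, n_dir)
      dir_pref[dir_cells] <- sample(c("left", "right"), n_dir, replace = TRUE)
    }
    frame_dir <- NULL
    if (any(dir_pref != "none")) {
      v <- c(0, diff(track$position[, 1]))
      v <- rolling_mean_centered(v, max(1L, round(0.5 * length(v) /
                                                    diff(range(track$timestamps)))))
      frame_dir <- ifelse(v > 0, "right", ifelse(v < 0, "left", "none"))
    }
    spikes <- matrix(0L, n_cells, n_frames)
    for (k in seq_len(n_cells)) {
      d2 <- rowSums((track$position -
                       matrix(centers[k, ], n_frames, track$ndim, byrow = TRUE))^2)
      rate <- baseline[k] + (p_max[k] - baseline[k]) *
        exp(-d2 / (2 * field_width_cm[k]^2))
      if (dir_pref[k] != "none") {
        rate[frame_dir != dir_pref[k]] <- baseline[k]
      }
      spikes[k, ] <- stats::rbinom(n_frames, 1L, rate)
    }
    gt <- data.frame(cell = seq_len(n_cells), center_x = centers[, 1])
    if (track$ndim == 2L) gt$center_y <- centers[, 2]
    gt$field_width <- field_width_cm
    gt$p_max <- p_max
    gt$baseline <- baseline
    gt$direction_pref <- dir_pref
    list(spikes = spikes, ground_truth = gt)
  })
}

#' Closed-form peak lag of the double-exponential transient kernel
#'
#' Time (s) from an event to the maximum of
#' `exp(-t/tau_decay) - exp(-t/tau_rise)`.
#' @param tau_rise_s,tau_decay_s kernel time constants, `tau_decay > tau_rise > 0`.
#' @return peak lag in seconds.
#' @export
calcium_kernel_peak_s <- function(tau_rise_s, tau_decay_s) {
  tau_rise_s * tau_decay_s / (tau_decay_s - tau_rise_s) *
    log(tau_decay_s / tau_rise_s)
}

#' Synthesize GCaMP-like calcium traces from binary events
#'
#' Every event adds a double-exponential transient
#' `amplitude * (exp(-t/tau_decay) - exp(-t/tau_rise))` from its frame
#' onward (fast rise, slow decay — GCaMP6f-like for the defaults), plus
#' additive white Gaussian noise. The synthesis is linear in events.
#'
#' @param spikes neuron x frame matrix of non-negative event counts.
#' @param sampling_rate_hz frame rate in Hz.
#' @param tau_rise_s,tau_decay_s kernel time constants (s), decay > rise > 0.
#' @param amplitude kernel scale (arbitrary fluorescence units).
#' @param noise_sd SD of the additive Gaussian noise.
#' @param seed integer seed for the noise.
#' @return A [calcium_traces()].
#' @export
synthesize_calcium <- function(spikes, sampling_rate_hz = 30, tau_rise_s = 0.1,
                               tau_decay_s = 1.0, amplitude = 1,
                               noise_sd = 0.1, seed = NULL) {
  spikes <- as.matrix(spikes)
  if (any(spikes < 0)) stop_invalid("spike counts must be non-negative")
  if (!(tau_decay_s > tau_rise_s && tau_rise_s > 0)) {
    stop_invalid("require tau_decay_s > tau_rise_s > 0")
  }
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  n_frames <- ncol(spikes)
  tk <- seq(0, max(8 * tau_decay_s, 2 / sampling_rate_hz), by = 1 / sampling_rate_hz)
  kernel <- amplitude * (exp(-tk / tau_decay_s) - exp(-tk / tau_rise_s))
  values <- t(apply(spikes, 1L, function(s) {
    if (!any(s > 0)) return(numeric(n_frames))
    y <- stats::convolve(s, rev(kernel), type = "open")
    y[seq_len(n_frames)]
  }))
  if (noise_sd > 0) {
    values <- values + with_seed_(seed, {
      matrix(stats::rnorm(length(values), 0, noise_sd), nrow(values))
    })
  }
  calcium_traces(values, sampling_rate_hz)
}

#' Generate a complete synthetic recording session
#'
#' Convenience wrapper producing behavior, ground-truth place-cell events,
#' and calcium traces on one shared frame clock. Defaults emulate the
#' recording conditions the package targets: a 15 min session at 30 Hz on a
#' 100 cm linear track (or a 45 x 45 cm open field), tens of Gaussian place
#' cells tiling the arena, GCaMP6f-like transients, and immobility bouts at
#' the reward ends.
#'
#' @param duration_s session length (s).
#' @param sampling_rate_hz frame rate (Hz).
#' @param geometry `"linear"` for a 1D track, `"open_field"` for a 2D arena.
#' @param track_length_cm linear track length (cm).
#' @param arena_cm open-field size (cm).
#' @param n_cells number of simulated cells.
#' @param mean_speed_cms mean running speed (cm/s).
#' @param pause_prob probability of an immobility pause at each track end.
#' @param field_width_cm,p_max,baseline,frac_directional per-cell tuning
#'   parameters, see [simulate_place_cells()].
#' @param tau_rise_s,tau_decay_s,amplitude,noise_sd transient parameters,
#'   see [synthesize_calcium()].
#' @param seed master seed; all stages derive their own seeds from it.
#' @return An object of class `synthetic_session`: `track`, `spikes`,
#'   `traces`, `ground_truth`, `seed`.
#' @export
simulate_session <- function(duration_s = 900, sampling_rate_hz = 30,
                             geometry = c("linear", "open_field"),
                             track_length_cm = 100, arena_cm = c(45, 45),
                             n_cells = 60, mean_speed_cms = 20,
                             pause_prob = 0.5, field_width_cm = 5,
                             p_max = 0.1, baseline = 0.01,
                             frac_directional = 0, tau_rise_s = 0.1,
                             tau_decay_s = 1.0, amplitude = 1, noise_sd = 0.1,
                             seed = 1L) {
  geometry <- match.arg(geometry)
  track <- if (geometry == "linear") {
    simulate_behavior_1d(duration_s, sampling_rate_hz, track_length_cm,
                         mean_speed_cms, pause_prob,
                         seed = derive_seed(seed, 1L))
  } else {
    simulate_behavior_2d(duration_s, sampling_rate_hz, arena_cm,
                         mean_speed_cms, seed = derive_seed(seed, 1L))
  }
  pc <- simulate_place_cells(track, n_cells, field_width_cm, p_max, baseline,
                             frac_directional, seed = derive_seed(seed, 2L))
  traces <- synthesize_calcium(pc$spikes, sampling_rate_hz, tau_rise_s,
                               tau_decay_s, amplitude, noise_sd,
                               seed = derive_seed(seed, 3L))
  structure(list(track = track, spikes = pc$spikes, traces = traces,
                 ground_truth = pc$ground_truth, seed = seed),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %d cells, %d frames, %dD arena, seed %d\n",
              nrow(x$spikes), ncol(x$spikes), x$track$ndim, x$seed))
  invisible(x)
}
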