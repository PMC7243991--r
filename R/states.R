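#' Discrete behavioral state sequence
#'
#' Per-frame discrete state ids in `1..M` (or `NA` for excluded frames),
#' together with the per-state geometry (bin centers in cm, bin extents,
#' optional direction labels) and the inclusion mask consumed by all
#' probability estimates. Excluded frames are ignored by every downstream
#' estimate (tuning, shuffles, bootstraps, decoding metrics).
#'
#' @param state integer vector of state ids in `1..M`, `NA` where excluded.
#' @param M number of states.
#' @param geometry data.frame with exactly `M` rows: `state`, center
#'   coordinates `x` (and `y` for 2D), bin extents, optional `direction`.
#' @param included logical per-frame inclusion mask; `NA` states are
#'   forced out of the mask.
#' @param ndim 1 or 2 spatial dimensions.
#' @param dims for 2D grids, `c(nx, ny)`.
#' @return An object of class `state_sequence`.
#' @export
state_sequence <- function(state, M, geometry, included = NULL,
                           ndim = 1L, dims = NULL) {
  state <- as.integer(state)
  if (anyNA(state[!is.na(state)])) stop_invalid("bad state ids")
  if (any(state < 1L | state > M, na.rm = TRUE)) {
    stop_invalid("state ids must lie in 1..M")
  }
  if (nrow(geometry) != M) stop_invalid("geometry must have exactly M rows")
  if (is.null(included)) included <- rep(TRUE, length(state))
  if (length(included) != length(state)) {
    stop_invalid("included mask length must match the frame count")
  }
  included <- included & !is.na(state)
  structure(list(state = state, M = as.integer(M), geometry = geometry,
                 included = included, ndim = as.integer(ndim), dims = dims),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf("<state_sequence> %d frames, M = %d (%dD), %.1f%% included\n",
              length(x$state), x$M, x$ndim, 100 * mean(x$included)))
  invisible(x)
}

#' Locomotor speed from a behavior track
#'
#' Euclidean displacement between consecutive samples divided by the time
#' step, boxcar-smoothed over `smooth_window_s`. The first frame copies the
#' second (its displacement is undefined).
#'
#' @param track a [behavior_track()].
#' @param smooth_window_s boxcar window in seconds (0 disables smoothing).
#' @return numeric vector of speeds (cm/s), one per sample.
#' @export
compute_speed <- function(track, smooth_window_s = 0.5) {
  stopifnot(inherits(track, "behavior_track"))
  if (length(track$timestamps) < 2L) stop_invalid("need at least 2 samples")
  dt <- diff(track$timestamps)
  if (any(dt <= 0)) stop_invalid("timestamps must be strictly increasing")
  disp <- sqrt(rowSums(diff(track$position)^2))
  speed <- c(NA_real_, disp / dt)
  speed[1] <- speed[2]
  if (smooth_window_s > 0) {
    width <- round(smooth_window_s / mean(dt))
    speed <- rolling_mean_centered(speed, width)
  }
  speed
}

#' Discretize a 1D track into spatial bins
#'
#' Bins are 0-based half-open intervals `[k*w, (k+1)*w)`; the far wall
#' clamps into the last bin, and when the track length is not divisible by
#' the bin width the last bin is narrower (`mode = "truncate"`, default) —
#' a 100 cm track at 3 cm gives M = 34 with a final 1 cm bin. With
#' `mode = "equal"` the track is instead split into `M = ceiling(L/w)` bins
#' of equal width `L/M`.
#'
#' @param track a 1D [behavior_track()].
#' @param bin_width_cm spatial bin width (cm, > 0).
#' @param mode `"truncate"` (last bin narrower) or `"equal"` (equal widths).
#' @return A [state_sequence()] whose geometry holds bin centers.
#' @export
discretize_1d <- function(track, bin_width_cm = 3,
                          mode = c("truncate", "equal")) {
  stopifnot(inherits(track, "behavior_track"))
  if (track$ndim != 1L) stop_invalid("discretize_1d needs a 1D track")
  check_scalar_number(bin_width_cm, "bin_width_cm", lower = 0, strict_lower = TRUE)
  mode <- match.arg(mode)
  L <- track$arena_bounds[1]
  M <- ceiling(L / bin_width_cm)
  w <- if (mode == "equal") L / M else bin_width_cm
  pos <- track$position[, 1]
  state <- pmin(floor(pos / w), M - 1L) + 1L
  state[is.na(pos)] <- NA_integer_
  lower <- (seq_len(M) - 1L) * w
  upper <- pmin(seq_len(M) * w, L)
  geometry <- data.frame(state = seq_len(M), x = (lower + upper) / 2,
                         width = upper - lower)
  state_sequence(state, M, geometry, ndim = 1L)
}

#' Discretize a 2D arena into a grid of spatial bins
#'
#' Row-major grid of `ceiling(W/bin) x ceiling(H/bin)` square bins; edge
#' bins clamp positions on the far walls, and are narrower when the arena
#' size is not divisible by the bin size.
#'
#' @param track a 2D [behavior_track()].
#' @param bin_cm spatial bin side (cm, > 0).
#' @return A [state_sequence()] with 2D bin centers and `dims = c(nx, ny)`.
#' @export
discretize_2d <- function(track, bin_cm = 3) {
  stopifnot(inherits(track, "behavior_track"))
  if (track$ndim != 2L) stop_invalid("discretize_2d needs a 2D track")
  check_scalar_number(bin_cm, "bin_cm", lower = 0, strict_lower = TRUE)
  W <- track$arena_bounds[1]; H <- track$arena_bounds[2]
  nx <- ceiling(W / bin_cm); ny <- ceiling(H / bin_cm)
  ix <- pmin(floor(track$position[, 1] / bin_cm), nx - 1L)
  iy <- pmin(floor(track$position[, 2] / bin_cm), ny - 1L)
  state <- iy * nx + ix + 1L
  state[is.na(ix) | is.na(iy)] <- NA_integer_
  gx <- rep(seq_len(nx), ny); gy <- rep(seq_len(ny), each = nx)
  lx <- (gx - 1L) * bin_cm; ux <- pmin(gx * bin_cm, W)
  ly <- (gy - 1L) * bin_cm; uy <- pmin(gy * bin_cm, H)
  geometry <- data.frame(state = seq_len(nx * ny),
                         x = (lx + ux) / 2, y = (ly + uy) / 2,
                         width_x = ux - lx, width_y = uy - ly)
  state_sequence(state, nx * ny, geometry, ndim = 2L, dims = c(nx, ny))
}

#' Augment 1D states with running direction
#'
#' Doubles the state space of a 1D sequence: frames traveling rightward
#' (smoothed velocity above `+min_dir_speed_cms`) keep their state `s`,
#' leftward frames map to `s + M`, and frames whose |velocity| is at or
#' below the floor are excluded rather than guessed. Used to capture the
#' unidirectionality of place fields on a linear track.
#'
#' @param stateseq a 1D [state_sequence()].
#' @param track the [behavior_track()] the sequence was built from.
#' @param min_dir_speed_cms direction-speed floor (cm/s).
#' @param smooth_window_s velocity smoothing window (s).
#' @return A [state_sequence()] with `2 * M` states and direction labels.
#' @export
augment_direction <- function(stateseq, track, min_dir_speed_cms = 2,
                              smooth_window_s = 0.5) {
  stopifnot(inherits(stateseq, "state_sequence"), inherits(track, "behavior_track"))
  if (stateseq$ndim != 1L || !is.null(stateseq$geometry$direction)) {
    stop_invalid("direction augmentation applies to plain 1D state sequences")
  }
  if (length(stateseq$state) != nrow(track$position)) {
    stop_invalid("state sequence and track must share the frame clock")
  }
  dt <- diff(track$timestamps)
  vel <- c(NA_real_, diff(track$position[, 1]) / dt)
  vel[1] <- vel[2]
  if (smooth_window_s > 0) {
    vel <- rolling_mean_centered(vel, round(smooth_window_s / mean(dt)))
  }
  M0 <- stateseq$M
  state <- stateseq$state
  state[vel < -min_dir_speed_cms] <- state[vel < -min_dir_speed_cms] + M0
  state[abs(vel) <= min_dir_speed_cms] <- NA_integer_
  geometry <- rbind(
    cbind(stateseq$geometry, direction = "right"),
    transform(stateseq$geometry, state = state + M0, direction = "left"))
  rownames(geometry) <- NULL
  state_sequence(state, 2L * M0, geometry,
                 included = stateseq$included, ndim = 1L)
}

#' Exclude immobility periods from a state sequence
#'
#' Marks frames with speed below `min_speed_cms` as excluded (union with
#' any existing exclusions — exclusion is monotone). Immobility periods can
#' contain activity tuned to internal rather than external variables
#' (e.g. replay), so they are removed before estimating spatial tuning.
#'
#' @param stateseq a [state_sequence()].
#' @param speed per-frame speed (cm/s), aligned to the sequence.
#' @param min_speed_cms immobility threshold (cm/s, default 5).
#' @return The sequence with an updated inclusion mask.
#' @export
exclude_immobility <- function(stateseq, speed, min_speed_cms = 5) {
  stopifnot(inherits(stateseq, "state_sequence"))
  if (length(speed) != length(stateseq$state)) {
    stop_invalid("speed must be aligned to the state sequence frames")
  }
  stateseq$included <- stateseq$included & !(speed < min_speed_cms)
  stateseq
}
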