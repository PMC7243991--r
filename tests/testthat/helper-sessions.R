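# Shared fixtures, built in code. Small sessions keep the unit suite fast;
# the acceptance tests build their own full-size sessions.

tiny_session <- function(seed = 42, duration_s = 120, n_cells = 12, ...) {
  simulate_session(duration_s = duration_s, n_cells = n_cells, seed = seed, ...)
}

# state sequence of a session with immobility excluded (1D)
session_states <- function(session, bin_width_cm = 3, min_speed_cms = 5) {
  st <- if (session$track$ndim == 1L) {
    discretize_1d(session$track, bin_width_cm)
  } else {
    discretize_2d(session$track, bin_width_cm)
  }
  exclude_immobility(st, compute_speed(session$track), min_speed_cms)
}

# hand-buildable state sequence over M states on a fake 1D geometry
toy_states <- function(state_ids, M, included = NULL, bin_width = 3) {
  geometry <- data.frame(state = seq_len(M),
                         x = (seq_len(M) - 0.5) * bin_width,
                         width = bin_width)
  state_sequence(state_ids, M, geometry, included = included, ndim = 1L)
}

# single-neuron raster from a 0/1 vector
toy_raster <- function(active, rate = 30) {
  binary_raster(matrix(as.integer(active), nrow = 1), rate, "rise")
}
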