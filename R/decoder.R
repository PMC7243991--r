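#' Naive Bayes decoder model
#'
#' Low-level constructor bundling the quantities the decoder scores with:
#' per-neuron tuning curves `P(A_k|S)`, marginals `P(A_k)`, and a state
#' prior `P(S)`. Most users should call [build_decoder()], which estimates
#' these from a training raster; the raw constructor exists for decoding
#' with externally supplied curves and for testing.
#'
#' Prior modes: `"uniform"` scores with a flat prior `1/M`; `"observed"`
#' uses the supplied occupancy prior; `"unbiased"` uses a flat prior and
#' replaces the marginal likelihood (the per-neuron activity bias) by 1.
#'
#' Scoring variants: `"log_product"` sums `log P(A_k|S) + log P(S) -
#' log P(A_k)` over active neurons, with a zero likelihood treated as
#' `-Inf` (certainty that the state is impossible); `"log1p"` sums
#' `log(1 + P(A_k|S) P(S) / P(A_k))`, a transform that avoids underflow by
#' letting small values converge to themselves. The two variants do not
#' generally rank states identically — `sum log(1+x_k)` does not order like
#' `prod x_k` — so they are kept strictly separate.
#'
#' @param likelihood neuron x M matrix `P(A_k|S)` (`NA` = undefined state).
#' @param marginal per-neuron `P(A_k)` (> 0).
#' @param prior observed occupancy prior `P(S)` (length M, sums to 1 over
#'   visited states).
#' @param prior_mode `"uniform"`, `"observed"`, or `"unbiased"`.
#' @param scoring_variant `"log_product"` or `"log1p"`.
#' @param geometry optional per-state geometry (bin centers), carried into
#'   error metrics.
#' @param sampling_rate frame rate (Hz), used to convert window seconds to
#'   frames.
#' @return An object of class `decoder_model`.
#' @export
decoder_model <- function(likelihood, marginal, prior,
                          prior_mode = c("uniform", "observed", "unbiased"),
                          scoring_variant = c("log_product", "log1p"),
                          geometry = NULL, sampling_rate = 30) {
  prior_mode <- match.arg(prior_mode)
  scoring_variant <- match.arg(scoring_variant)
  likelihood <- as.matrix(likelihood)
  N <- nrow(likelihood); M <- ncol(likelihood)
  if (N < 1L) stop_invalid("decoder needs at least one neuron")
  if (length(marginal) != N) stop_invalid("one marginal per neuron required")
  if (any(marginal <= 0)) {
    stop_invalid("neurons with zero marginal cannot contribute evidence")
  }
  if (length(prior) != M) stop_invalid("prior must have one entry per state")
  valid_states <- apply(!is.na(likelihood), 2L, all) & prior >= 0
  if (!any(valid_states)) stop_invalid("no state with defined tuning")
  structure(list(likelihood = likelihood, marginal = as.numeric(marginal),
                 prior = as.numeric(prior), prior_mode = prior_mode,
                 scoring_variant = scoring_variant,
                 valid_states = valid_states, N = N, M = M,
                 geometry = geometry, sampling_rate = sampling_rate),
            class = "decoder_model")
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf("<decoder_model> %d neurons x %d states (%d decodable), %s prior, %s scoring\n",
              x$N, x$M, sum(x$valid_states), x$prior_mode, x$scoring_variant))
  invisible(x)
}

#' Restrict a state sequence to a frame mask
#'
#' Intersects the inclusion mask with `mask` — used to confine tuning
#' estimation to training epochs or metrics to test epochs.
#'
#' @param stateseq a [state_sequence()].
#' @param mask logical per-frame vector.
#' @return the restricted sequence.
#' @export
restrict_states <- function(stateseq, mask) {
  stopifnot(inherits(stateseq, "state_sequence"))
  if (length(mask) != length(stateseq$state)) stop_invalid("mask length mismatch")
  stateseq$included <- stateseq$included & mask
  stateseq
}

#' Train a naive Bayes decoder from a binary raster
#'
#' Estimates per-neuron tuning (see [estimate_tuning()]) on the included
#' frames of `stateseq_train` and wraps it into a [decoder_model()].
#' Neurons never active in training carry no evidence and are dropped with
#' a warning; training states with zero occupancy are removed from the
#' decodable state space.
#'
#' @param raster_train a [binary_raster()] (training frames selected via
#'   the state sequence's inclusion mask, e.g. [restrict_states()]).
#' @param stateseq_train a [state_sequence()].
#' @inheritParams decoder_model
#' @return A [decoder_model()]; attribute `kept_neurons` maps its rows back
#'   to the raster rows.
#' @export
build_decoder <- function(raster_train, stateseq_train,
                          prior_mode = c("uniform", "observed", "unbiased"),
                          scoring_variant = c("log_product", "log1p")) {
  tuning <- estimate_tuning(raster_train, stateseq_train)
  keep <- tuning$marginal > 0
  if (!any(keep)) stop_invalid("no neuron active in the training epochs")
  if (!all(keep)) {
    warning(sprintf("%d neuron(s) never active in training dropped", sum(!keep)),
            call. = FALSE)
  }
  model <- decoder_model(tuning$likelihood[keep, , drop = FALSE],
                         tuning$marginal[keep], tuning$prior,
                         prior_mode = prior_mode,
                         scoring_variant = scoring_variant,
                         geometry = tuning$geometry,
                         sampling_rate = raster_train$sampling_rate)
  attr(model, "kept_neurons") <- which(keep)
  model
}

# effective prior / marginal under the model's prior_mode
decoder_effective_terms <- function(model) {
  prior <- switch(model$prior_mode,
                  uniform = rep(1 / model$M, model$M),
                  observed = model$prior,
                  unbiased = rep(1 / model$M, model$M))
  marginal <- if (model$prior_mode == "unbiased") {
    rep(1, model$N)
  } else {
    model$marginal
  }
  list(prior = prior, marginal = marginal)
}

#' Decode behavioral states from multi-neuron activity
#'
#' Frame-by-frame naive Bayes decoding: at each frame, evidence is
#' accumulated over the neurons *active* at that frame (an active neuron's
#' tuning curve says where the animal likely is; inactive neurons are
#' silent witnesses and contribute nothing by default). With `window_s > 0`
#' the per-frame log-scores of `L = round(window_s * rate)` temporally
#' adjacent frames are summed — the product of temporally adjacent
#' posteriors — which suppresses erratic frame-to-frame jumps at the cost
#' of temporal resolution. Scores are exponentiated and normalized into a
#' posterior per frame.
#'
#' By default the window is *centered* on the current frame (zero-phase,
#' like the low-pass filter in the binarization stage): a purely causal
#' window of past frames delays the pooled evidence by `L/2` frames, which
#' at running speed `v` translates into a systematic decoding lag of
#' `v * window_s / 2` cm (5 cm at 20 cm/s and 0.5 s) — enough to *increase*
#' the decoding error that the filter is meant to reduce. The causal
#' variant (`window_mode = "past"`) is retained for strictly real-time
#' decoding semantics.
#'
#' Frames with no active neuron anywhere in the window carry no evidence:
#' they receive the prior as posterior and are flagged undecodable (their
#' MAP state is `NA`). The same applies to the degenerate case where every
#' state is ruled impossible by a zero likelihood.
#'
#' @param raster_test a [binary_raster()] with the model's neuron set.
#' @param model a [decoder_model()].
#' @param window_s temporal filtering window in seconds (>= 0; 0 = none).
#' @param window_mode `"centered"` (zero-phase, default) or `"past"`
#'   (causal, current frame plus the `L - 1` preceding ones).
#' @return An object of class `posterior_trajectory`: `posteriors` (frame x
#'   M, rows summing to 1 on decodable frames; invalid states get 0),
#'   `map_state` (per-frame MAP state id or `NA`), `decodable`,
#'   `n_active` (active-neuron count per window), `window_frames`.
#' @export
decode_posteriors <- function(raster_test, model, window_s = 0,
                              window_mode = c("centered", "past")) {
  stopifnot(inherits(raster_test, "binary_raster"), inherits(model, "decoder_model"))
  window_mode <- match.arg(window_mode)
  if (window_s < 0) stop_invalid("window_s must be >= 0")
  A <- raster_test$states
  if (nrow(A) != model$N) {
    stop_invalid("raster has %d neurons but the model expects %d",
                 nrow(A), model$N)
  }
  eff <- decoder_effective_terms(model)
  vs <- which(model$valid_states)
  Mv <- length(vs)
  lik <- model$likelihood[, vs, drop = FALSE]
  log_prior_row <- log(eff$prior[vs])
  T_ <- ncol(A)
  tA <- t(A)
  if (model$scoring_variant == "log_product") {
    W <- log(ifelse(lik > 0, lik, 1)) - log(eff$marginal) +
      matrix(log_prior_row, model$N, Mv, byrow = TRUE)
    Z <- (lik == 0) * 1
    Sc <- tA %*% W
    Zc <- tA %*% Z
  } else {
    x <- lik * matrix(eff$prior[vs], model$N, Mv, byrow = TRUE) / eff$marginal
    W <- log1p(x)
    Sc <- tA %*% W
    Zc <- matrix(0, T_, Mv)
  }
  n_active <- rowSums(tA)
  L <- max(1L, round(window_s * raster_test$sampling_rate))
  if (L > 1L) {
    Sc <- rolling_sum(Sc, L, window_mode)
    Zc <- rolling_sum(Zc, L, window_mode)
    n_active <- as.numeric(rolling_sum(cbind(n_active), L, window_mode))
  }
  decodable <- n_active > 0
  Sc[Zc > 0] <- -Inf
  if (model$scoring_variant == "log_product") {
    mx <- row_max_values(Sc)
    degenerate <- !is.finite(mx)
    P <- exp(Sc - ifelse(is.finite(mx), mx, 0))
  } else {
    P <- expm1(Sc)
    degenerate <- rowSums(P) == 0
  }
  decodable <- decodable & !degenerate
  prior_row <- eff$prior[vs] / sum(eff$prior[vs])
  if (any(!decodable)) {
    P[!decodable, ] <- matrix(prior_row, sum(!decodable), Mv, byrow = TRUE)
  }
  P <- P / rowSums(P)
  map_v <- max.col(P, ties.method = "first")
  posteriors <- matrix(0, T_, model$M)
  posteriors[, vs] <- P
  map_state <- ifelse(decodable, vs[map_v], NA_integer_)
  structure(list(posteriors = posteriors, map_state = as.integer(map_state),
                 decodable = decodable, n_active = n_active,
                 window_frames = L, window_mode = window_mode,
                 prior_mode = model$prior_mode,
                 scoring_variant = model$scoring_variant,
                 geometry = model$geometry),
            class = "posterior_trajectory")
}

#' @export
print.posterior_trajectory <- function(x, ...) {
  cat(sprintf("<posterior_trajectory> %d frames x %d states, window %d frame(s), %d undecodable\n",
              nrow(x$posteriors), ncol(x$posteriors), x$window_frames,
              sum(!x$decodable)))
  invisible(x)
}

#' Maximum a posteriori state per frame
#'
#' Argmax of each posterior row; ties break to the lowest state index for
#' cross-platform determinism. For a [decode_posteriors()] result the
#' stored MAP sequence is returned (undecodable frames are `NA` there,
#' even though their rows hold the prior).
#'
#' @param posteriors a frame x M matrix or a `posterior_trajectory`.
#' @return integer vector of decoded state ids (`NA` where undefined).
#' @export
map_estimate <- function(posteriors) {
  if (inherits(posteriors, "posterior_trajectory")) {
    return(posteriors$map_state)
  }
  P <- as.matrix(posteriors)
  out <- rep(NA_integer_, nrow(P))
  ok <- apply(P, 1L, function(r) any(!is.na(r)))
  if (any(ok)) {
    Pok <- P[ok, , drop = FALSE]
    Pok[is.na(Pok)] <- -Inf
    out[ok] <- max.col(Pok, ties.method = "first")
  }
  out
}

#' Decoding agreement
#'
#' Fraction of decodable frames whose exact state was decoded — a
#' conservative metric: decoding one bin away from the truth counts as a
#' miss. Frames where either vector is `NA` (undecodable or excluded) are
#' skipped.
#'
#' @param decoded,actual aligned integer state vectors.
#' @return scalar in `[0, 1]`.
#' @export
decoding_agreement <- function(decoded, actual) {
  if (length(decoded) != length(actual)) stop_invalid("length mismatch")
  ok <- !is.na(decoded) & !is.na(actual)
  if (!any(ok)) stop_invalid("no decodable frames to score")
  mean(decoded[ok] == actual[ok])
}

#' Decoding error in cm
#'
#' Euclidean distance between the decoded and actual bin centers per frame,
#' with mean and median summaries. Frames with an undefined decoded or
#' actual state are skipped and counted.
#'
#' @param decoded,actual aligned integer state vectors.
#' @param geometry per-state geometry with bin centers (`x`, optionally
#'   `y`), as carried by state sequences, tuning models, and decoders.
#' @return list with `per_frame_cm` (NA on skipped frames), `mean_cm`,
#'   `median_cm`, `n_scored`, `n_skipped`.
#' @export
decoding_error <- function(decoded, actual, geometry) {
  if (length(decoded) != length(actual)) stop_invalid("length mismatch")
  centers <- as.matrix(geometry[, intersect(c("x", "y"), names(geometry)),
                                drop = FALSE])
  ok <- !is.na(decoded) & !is.na(actual)
  err <- rep(NA_real_, length(decoded))
  if (any(ok)) {
    d <- centers[decoded[ok], , drop = FALSE] - centers[actual[ok], , drop = FALSE]
    err[ok] <- sqrt(rowSums(d^2))
  }
  list(per_frame_cm = err,
       mean_cm = mean(err[ok]),
       median_cm = stats::median(err[ok]),
       n_scored = sum(ok), n_skipped = sum(!ok))
}

#' Confusion matrix of decoded vs actual states
#'
#' Entry `(d, a)` is the fraction of frames with actual state `a` decoded
#' as `d`; columns of visited states sum to 1, unvisited columns are
#' all-zero and flagged in the `visited` attribute.
#'
#' @param decoded,actual aligned integer state vectors (`NA` skipped).
#' @param M number of states.
#' @return M x M matrix (rows = decoded, columns = actual) with a logical
#'   `visited` attribute per column.
#' @export
confusion_matrix <- function(decoded, actual, M) {
  if (length(decoded) != length(actual)) stop_invalid("length mismatch")
  ok <- !is.na(decoded) & !is.na(actual)
  d <- decoded[ok]; a <- actual[ok]
  if (any(c(d, a) < 1L | c(d, a) > M)) stop_invalid("state id out of range 1..M")
  cm <- matrix(0, M, M)
  counts <- table(factor(d, levels = seq_len(M)), factor(a, levels = seq_len(M)))
  cm[] <- as.numeric(counts)
  colsum <- colSums(cm)
  visited <- colsum > 0
  cm[, visited] <- sweep(cm[, visited, drop = FALSE], 2L, colsum[visited], "/")
  attr(cm, "visited") <- visited
  cm
}

#' Split a session into non-overlapping train/test epochs
#'
#' The session is cut into contiguous blocks of `block_s` seconds; blocks
#' are randomly assigned to the training set until its included-frame count
#' reaches `train_fraction` of all included frames, and the remainder forms
#' the test set. Excluded frames (immobility etc.) belong to neither mask.
#' Block-wise (rather than frame-wise) assignment keeps calcium transients
#' intact within an epoch.
#'
#' @param n_frames total frame count.
#' @param included_mask logical per-frame inclusion mask.
#' @param train_fraction target included-frame fraction for training, in (0, 1).
#' @param block_s epoch block length in seconds (default 5).
#' @param rate frame rate in Hz.
#' @param n_trials number of independent splits.
#' @param seed integer seed.
#' @return list of `n_trials` elements, each `list(train =, test =)`
#'   disjoint logical masks.
#' @export
split_epochs <- function(n_frames, included_mask, train_fraction = 0.5,
                         block_s = 5, rate = 30, n_trials = 1, seed = NULL) {
  check_scalar_number(train_fraction, "train_fraction", lower = 0, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  if (length(included_mask) != n_frames) stop_invalid("mask length mismatch")
  bl <- max(1L, round(block_s * rate))
  block_of <- (seq_len(n_frames) - 1L) %/% bl + 1L
  n_blocks <- max(block_of)
  if (n_blocks < 2L) stop_invalid("need at least 2 blocks; shorten block_s")
  inc_per_block <- tabulate(block_of[included_mask], n_blocks)
  total_inc <- sum(inc_per_block)
  if (total_inc < 1L) stop_invalid("no included frames to split")
  target <- train_fraction * total_inc
  with_seed_(seed, {
    lapply(seq_len(n_trials), function(i) {
      perm <- sample.int(n_blocks)
      cum <- cumsum(inc_per_block[perm])
      k <- which(cum >= target)[1L]
      if (is.na(k)) k <- n_blocks - 1L
      k <- min(k, n_blocks - 1L)  # keep at least one block for testing
      train_blocks <- perm[seq_len(k)]
      train <- included_mask & block_of %in% train_blocks
      test <- included_mask & !train
      list(train = train, test = test)
    })
  })
}

# agreement / error of a trajectory against the truth, over `mask` frames
score_decoding <- function(traj, stateseq, mask = NULL) {
  decoded <- traj$map_state
  actual <- stateseq$state
  sel <- stateseq$included
  if (!is.null(mask)) sel <- sel & mask
  decoded[!sel] <- NA_integer_
  actual[!sel] <- NA_integer_
  err <- decoding_error(decoded, actual, stateseq$geometry)
  list(agreement = decoding_agreement(decoded, actual),
       mean_error_cm = err$mean_cm, median_error_cm = err$median_cm,
       n_scored = err$n_scored)
}

#' Decoding report over train/test trials
#'
#' Repeats the full train/decode/score cycle over `n_trials` independent
#' epoch splits and aggregates agreement, error, and the confusion matrix
#' (pooled over trials, test frames only).
#'
#' @param raster a [binary_raster()].
#' @param stateseq a [state_sequence()] (immobility already excluded).
#' @inheritParams decoder_model
#' @inheritParams split_epochs
#' @param window_s temporal filtering window (s).
#' @return An object of class `decoding_report` with `per_trial`
#'   (data.frame), `agreement` / `mean_error_cm` / `median_error_cm`
#'   (trial means), and `confusion`.
#' @export
decoding_report <- function(raster, stateseq, prior_mode = "uniform",
                            scoring_variant = "log_product", window_s = 0.5,
                            train_fraction = 0.5, block_s = 5, n_trials = 5,
                            seed = NULL) {
  splits <- split_epochs(ncol(raster$states), stateseq$included,
                         train_fraction, block_s, raster$sampling_rate,
                         n_trials, seed)
  rows <- vector("list", n_trials)
  pooled_d <- integer(0); pooled_a <- integer(0)
  for (i in seq_len(n_trials)) {
    model <- build_decoder(raster, restrict_states(stateseq, splits[[i]]$train),
                           prior_mode, scoring_variant)
    traj <- decode_posteriors(raster, model, window_s)
    sc <- score_decoding(traj, stateseq, splits[[i]]$test)
    rows[[i]] <- data.frame(trial = i, agreement = sc$agreement,
                            mean_error_cm = sc$mean_error_cm,
                            median_error_cm = sc$median_error_cm,
                            n_scored = sc$n_scored)
    sel <- splits[[i]]$test & stateseq$included & !is.na(traj$map_state)
    pooled_d <- c(pooled_d, traj$map_state[sel])
    pooled_a <- c(pooled_a, stateseq$state[sel])
  }
  per_trial <- do.call(rbind, rows)
  structure(list(per_trial = per_trial,
                 agreement = mean(per_trial$agreement),
                 mean_error_cm = mean(per_trial$mean_error_cm),
                 median_error_cm = mean(per_trial$median_error_cm),
                 confusion = confusion_matrix(pooled_d, pooled_a, stateseq$M),
                 n_trials = n_trials, window_s = window_s,
                 prior_mode = prior_mode, scoring_variant = scoring_variant),
            class = "decoding_report")
}

#' @export
print.decoding_report <- function(x, ...) {
  cat(sprintf("<decoding_report> %d trials, %s prior, window %.2g s\n",
              x$n_trials, x$prior_mode, x$window_s))
  cat(sprintf("  agreement %.3f, mean error %.2f cm, median error %.2f cm\n",
              x$agreement, x$mean_error_cm, x$median_error_cm))
  invisible(x)
}

#' Parameter sweep over one decoding knob
#'
#' Sweeps exactly one of `window_s`, `n_cells`, `train_fraction`,
#' `noise_fraction`, or `smooth_sigma` while holding the others at their
#' baseline; for each grid value x trial a fresh epoch split is drawn, a
#' decoder is trained (on a random cell subset for the `n_cells` axis;
#' noise injection / Gaussian smoothing are applied to the trained curves
#' before decoding), and agreement and error are scored on the test
#' frames.
#'
#' @param raster a [binary_raster()].
#' @param stateseq a [state_sequence()] (immobility already excluded).
#' @param grid named list with exactly one element, e.g.
#'   `list(window_s = c(0, 0.5, 1, 2))`.
#' @param n_trials independent splits per grid value (default 30).
#' @param seed master seed.
#' @param window_s,train_fraction,block_s,prior_mode,scoring_variant
#'   baseline decoding parameters.
#' @return tidy data.frame: `parameter`, `value`, `trial`, `agreement`,
#'   `mean_error_cm`, `median_error_cm`.
#' @export
run_sweep <- function(raster, stateseq, grid, n_trials = 30, seed = 1L,
                      window_s = 0.5, train_fraction = 0.5, block_s = 5,
                      prior_mode = "uniform", scoring_variant = "log_product") {
  axes <- c("window_s", "n_cells", "train_fraction", "noise_fraction",
            "smooth_sigma")
  if (!is.list(grid) || length(grid) != 1L || !(names(grid) %in% axes)) {
    stop_invalid("grid must be a named list varying exactly one of: %s",
                 paste(axes, collapse = ", "))
  }
  axis <- names(grid)
  values <- grid[[1L]]
  if (length(values) < 1L) stop_invalid("empty grid")
  n_frames <- ncol(raster$states)
  rows <- vector("list", length(values) * n_trials)
  r <- 0L
  for (vi in seq_along(values)) {
    v <- values[vi]
    for (trial in seq_len(n_trials)) {
      r <- r + 1L
      sd_ <- derive_seed(seed, vi * 1000L + trial)
      split <- split_epochs(n_frames, stateseq$included,
                            if (axis == "train_fraction") v else train_fraction,
                            block_s, raster$sampling_rate, 1L, sd_)[[1L]]
      rs <- raster
      if (axis == "n_cells") {
        cells <- with_seed_(derive_seed(sd_, 7L),
                            sample.int(nrow(raster$states), v))
        rs$states <- raster$states[cells, , drop = FALSE]
      }
      tuning <- estimate_tuning(rs, restrict_states(stateseq, split$train))
      if (axis == "noise_fraction") {
        tuning <- inject_noise(tuning, v, seed = derive_seed(sd_, 8L))
      }
      if (axis == "smooth_sigma") tuning <- smooth_tuning(tuning, v)
      keep <- tuning$marginal > 0
      model <- decoder_model(tuning$likelihood[keep, , drop = FALSE],
                             tuning$marginal[keep], tuning$prior,
                             prior_mode, scoring_variant,
                             geometry = tuning$geometry,
                             sampling_rate = raster$sampling_rate)
      rk <- rs; rk$states <- rs$states[keep, , drop = FALSE]
      traj <- decode_posteriors(rk, model,
                                if (axis == "window_s") v else window_s)
      sc <- score_decoding(traj, stateseq, split$test)
      rows[[r]] <- data.frame(parameter = axis, value = v, trial = trial,
                              agreement = sc$agreement,
                              mean_error_cm = sc$mean_error_cm,
                              median_error_cm = sc$median_error_cm)
    }
  }
  do.call(rbind, rows)
}
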