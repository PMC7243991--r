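#' Probabilistic tuning model for a set of neurons
#'
#' Estimated by frame counting over *included* frames only:
#' \describe{
#'   \item{marginal `P(A)`}{fraction of frames each neuron is active — the
#'     marginal likelihood (one scalar per neuron).}
#'   \item{prior `P(S)`}{fraction of time in each state — the occupancy
#'     prior (length `M`).}
#'   \item{joint `P(S, A)`}{probability of being active (and, separately,
#'     inactive) in each state (neuron x `M` matrices).}
#'   \item{likelihood `P(A|S)`}{probability of being active given the
#'     state — the tuning curve (neuron x `M`).}
#'   \item{mi}{mutual information between binary activity and state, bits.}
#' }
#' States with zero occupancy carry an explicit `NA` ("undefined") in the
#' likelihood — a 0 would claim certain silence — and are skipped by MI,
#' smoothing, and decoding.
#'
#' @param raster a [binary_raster()].
#' @param stateseq a [state_sequence()] on the same frame clock.
#' @return An object of class `tuning_model` with fields `marginal`,
#'   `prior`, `joint_active`, `joint_inactive`, `likelihood`, `mi`,
#'   `occupancy` (frame counts per state), `n_included`, `M`, `n_neurons`,
#'   `geometry`, `ndim`, `dims`.
#' @export
estimate_tuning <- function(raster, stateseq) {
  stopifnot(inherits(raster, "binary_raster"), inherits(stateseq, "state_sequence"))
  if (ncol(raster$states) != length(stateseq$state)) {
    stop_invalid("raster and state sequence must share the frame clock")
  }
  inc <- stateseq$included
  n_inc <- sum(inc)
  if (n_inc < 1L) stop_invalid("no included frames to estimate tuning from")
  st <- stateseq$state[inc]
  A <- raster$states[, inc, drop = FALSE]
  M <- stateseq$M
  occupancy <- tabulate(st, M)
  ind <- matrix(0, n_inc, M)
  ind[cbind(seq_len(n_inc), st)] <- 1
  active_counts <- A %*% ind                     # neuron x M
  marginal <- rowSums(A) / n_inc
  prior <- occupancy / n_inc
  joint_active <- active_counts / n_inc
  occ_mat <- matrix(occupancy, nrow(A), M, byrow = TRUE)
  likelihood <- ifelse(occ_mat > 0, active_counts / occ_mat, NA_real_)
  joint_inactive <- ifelse(occ_mat > 0,
                           (occ_mat - active_counts) / n_inc, NA_real_)
  joint_active[occ_mat == 0] <- NA_real_
  model <- structure(
    list(marginal = as.numeric(marginal), prior = prior,
         joint_active = joint_active, joint_inactive = joint_inactive,
         likelihood = likelihood, occupancy = occupancy,
         n_included = n_inc, M = M, n_neurons = nrow(A),
         geometry = stateseq$geometry, ndim = stateseq$ndim,
         dims = stateseq$dims, smoothed_sigma = 0, noise_fraction = 0),
    class = "tuning_model")
  model$mi <- mutual_info(model)
  model
}

#' @export
print.tuning_model <- function(x, ...) {
  cat(sprintf("<tuning_model> %d neurons x %d states, %d included frames\n",
              x$n_neurons, x$M, x$n_included))
  cat(sprintf("  MI [bits]: median %.3g, max %.3g; visited states: %d/%d\n",
              stats::median(x$mi), max(x$mi), sum(x$occupancy > 0), x$M))
  invisible(x)
}

#' Posterior state distribution given activity
#'
#' Bayes' rule with the empirical quantities:
#' `P(S_i | A) = P(A | S_i) * P(S_i) / P(A)`. Because the terms are plug-in
#' frequencies from the same frames, each neuron's posterior sums to
#' exactly 1 whenever its marginal is positive. Undefined (never-visited)
#' states contribute 0; never-active neurons get an all-`NA` posterior and
#' a warning.
#'
#' @param model a [estimate_tuning()] result.
#' @return neuron x M matrix of posterior probabilities.
#' @export
posterior_from_tuning <- function(model) {
  stopifnot(inherits(model, "tuning_model"))
  post <- matrix(NA_real_, model$n_neurons, model$M)
  silent <- model$marginal == 0
  if (any(silent)) {
    warning(sprintf("%d neuron(s) never active: posterior undefined",
                    sum(silent)), call. = FALSE)
  }
  lik <- model$likelihood
  lik[is.na(lik)] <- 0
  for (k in which(!silent)) {
    post[k, ] <- lik[k, ] * model$prior / model$marginal[k]
  }
  post
}

#' Mutual information between binary activity and state
#'
#' `MI = sum_i sum_j P(S_i, A_j) log2( P(S_i, A_j) / (P(S_i) P(A_j)) )`
#' over the visited states `i` and the two activity levels `j` (active /
#' inactive), with the convention `0 * log 0 = 0`.
#'
#' @param model a [estimate_tuning()] result.
#' @return numeric vector of MI values (bits), one per neuron.
#' @export
mutual_info <- function(model) {
  stopifnot(inherits(model, "tuning_model"))
  visited <- model$occupancy > 0
  prior <- model$prior[visited]
  term <- function(joint, pA_j) {
    # joint: neuron x visited-states slice; pA_j: per-neuron P(A = j)
    r <- joint * log2(joint /
      (matrix(prior, nrow(joint), length(prior), byrow = TRUE) * pA_j))
    r[joint == 0] <- 0
    rowSums(r)
  }
  ja <- model$joint_active[, visited, drop = FALSE]
  ji <- model$joint_inactive[, visited, drop = FALSE]
  mi <- term(ja, model$marginal) + term(ji, 1 - model$marginal)
  # marginal exactly 0 or 1: the degenerate activity level has P = 0
  mi[!is.finite(mi)] <- 0
  pmax(mi, 0)
}

gaussian_kernel_weights_1d <- function(M, sigma) {
  halo <- ceiling(4 * sigma)
  offs <- -halo:halo
  w <- exp(-offs^2 / (2 * sigma^2))
  list(offsets = offs, weights = w)
}

smooth_curve <- function(vals, sigma, ndim, dims) {
  defined <- !is.na(vals)
  v0 <- ifelse(defined, vals, 0)
  if (ndim == 1L) {
    kw <- gaussian_kernel_weights_1d(length(vals), sigma)
    M <- length(vals)
    num <- numeric(M); den <- numeric(M)
    for (j in seq_along(kw$offsets)) {
      idx <- seq_len(M) + kw$offsets[j]
      ok <- idx >= 1L & idx <= M
      w <- kw$weights[j]
      num[ok] <- num[ok] + w * v0[idx[ok]] * defined[idx[ok]]
      den[ok] <- den[ok] + w * defined[idx[ok]]
    }
  } else {
    nx <- dims[1]; ny <- dims[2]
    vm <- matrix(v0, ny, nx, byrow = TRUE)
    dm <- matrix(as.numeric(defined), ny, nx, byrow = TRUE)
    halo <- ceiling(4 * sigma)
    offs <- -halo:halo
    w1 <- exp(-offs^2 / (2 * sigma^2))
    conv2_sep <- function(m) {
      # separable truncated-Gaussian convolution with zero padding
      tmp <- matrix(0, nrow(m), ncol(m))
      for (j in seq_along(offs)) {
        idx <- seq_len(ncol(m)) + offs[j]
        ok <- idx >= 1L & idx <= ncol(m)
        tmp[, ok] <- tmp[, ok] + w1[j] * m[, idx[ok]]
      }
      out <- matrix(0, nrow(m), ncol(m))
      for (j in seq_along(offs)) {
        idx <- seq_len(nrow(m)) + offs[j]
        ok <- idx >= 1L & idx <= nrow(m)
        out[ok, ] <- out[ok, ] + w1[j] * tmp[idx[ok], ]
      }
      out
    }
    num <- as.vector(t(conv2_sep(vm * dm)))
    den <- as.vector(t(conv2_sep(dm)))
  }
  out <- rep(NA_real_, length(vals))
  out[defined] <- num[defined] / den[defined]
  out
}

#' Gaussian smoothing of tuning curves
#'
#' Convolves each neuron's likelihood with a normalized, truncated
#' (+/- 4 sigma) Gaussian kernel — along the track for 1D models,
#' separably over the grid for 2D maps. Undefined (zero-occupancy) states
#' are excluded from the kernel support and the kernel is renormalized over
#' the defined bins, including at boundaries (no wraparound: tracks and
#' arenas are not circular). `sigma_bins = 0` returns the model unchanged.
#'
#' Smoothing is a display/ablation device: it is applied to the likelihood
#' only, leaving the counting quantities untouched.
#'
#' @param model a [estimate_tuning()] result.
#' @param sigma_bins Gaussian SD in bins (>= 0).
#' @return The model with a smoothed likelihood.
#' @export
smooth_tuning <- function(model, sigma_bins) {
  stopifnot(inherits(model, "tuning_model"))
  check_scalar_number(sigma_bins, "sigma_bins", lower = 0)
  if (sigma_bins == 0) return(model)
  model$likelihood <- t(apply(model$likelihood, 1L, smooth_curve,
                              sigma = sigma_bins, ndim = model$ndim,
                              dims = model$dims))
  model$smoothed_sigma <- sigma_bins
  model
}

#' Replace part of the tuning curves with random values
#'
#' Robustness ablation: exactly `round(fraction * M)` likelihood entries
#' per neuron, chosen uniformly among the defined entries, are replaced by
#' independent Uniform(0, 1) draws. The prior and marginals are untouched,
#' and undefined states keep their marker (corrupting a curve must not
#' enlarge the decodable state space).
#'
#' @param model a [estimate_tuning()] result.
#' @param fraction fraction of the `M` entries to replace, in `[0, 1]`.
#' @param seed integer seed.
#' @return The model with a corrupted likelihood.
#' @export
inject_noise <- function(model, fraction, seed = NULL) {
  stopifnot(inherits(model, "tuning_model"))
  check_scalar_number(fraction, "fraction", lower = 0, upper = 1)
  n_replace <- round(fraction * model$M)
  if (n_replace == 0L) return(model)
  model$likelihood <- with_seed_(seed, {
    t(apply(model$likelihood, 1L, function(v) {
      defined <- which(!is.na(v))
      take <- min(n_replace, length(defined))
      idx <- sample(defined, take)
      v[idx] <- stats::runif(take)
      v
    }))
  })
  model$noise_fraction <- fraction
  model
}
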