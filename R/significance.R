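# Null-hypothesis testing for tuning statistics: circular-permutation
# surrogates (p-values) and bootstrap resampling (confidence intervals).
# Both are generic over the statistic (likelihood curve or MI) and operate
# on one neuron's binary activity row at a time.

# statistic of one activity row against a state sequence, given the
# precomputed occupancy; `act_idx` are the active frame indices (full
# frame space, before the inclusion mask).
stat_from_active_idx <- function(act_idx, st, inc, occ, n_inc, statistic) {
  sel <- act_idx[inc[act_idx]]
  counts <- tabulate(st[sel], length(occ))
  if (statistic == "likelihood_curve") {
    ifelse(occ > 0, counts / occ, NA_real_)
  } else {
    mi_from_counts(counts, occ, n_inc)
  }
}

mi_from_counts <- function(active_counts, occ, n_inc) {
  v <- occ > 0
  ja <- active_counts[v] / n_inc
  ji <- (occ[v] - active_counts[v]) / n_inc
  prior <- occ[v] / n_inc
  pA <- sum(active_counts[v]) / n_inc
  term <- function(j, p) {
    t <- j * log2(j / (prior * p))
    t[j == 0] <- 0
    t
  }
  if (pA <= 0 || pA >= 1) return(0)
  max(sum(term(ja, pA)) + sum(term(ji, 1 - pA)), 0)
}

#' Circular-permutation null distribution of a tuning statistic
#'
#' For each surrogate the neuron's binary activity vector is rotated in
#' time by a shift drawn uniformly from `1..T-1` (the identity shift is
#' excluded), and the statistic is recomputed against the untouched state
#' sequence. Rotation happens in the original frame space *before* the
#' inclusion mask is applied, so the temporal structure of calcium
#' transients is preserved while the activity-behavior relationship is
#' destroyed — a conservative null compared to frame-wise randomization.
#' Every surrogate conserves the total active-frame count.
#'
#' @param raster_row binary activity vector of one neuron (0/1, length =
#'   frame count), or a 1-row slice of a raster's `states`.
#' @param stateseq a [state_sequence()] on the same frame clock.
#' @param statistic `"likelihood_curve"` (per-state `P(A|S)`) or `"mi"`.
#' @param n_shuffles number of surrogates (default 1000).
#' @param seed integer seed; fixed seed reproduces the surrogates exactly.
#' @return An object of class `shuffle_distribution`: `statistic_name`,
#'   `actual` (length `M` or 1), `surrogates` (`n_shuffles` x `M` or 1),
#'   `shifts`.
#' @export
circular_shuffle_statistic <- function(raster_row, stateseq,
                                       statistic = c("likelihood_curve", "mi"),
                                       n_shuffles = 1000, seed = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(stateseq, "state_sequence"))
  row <- as.integer(raster_row)
  T_ <- length(row)
  if (T_ < 2L) stop_invalid("need at least 2 frames to permute")
  if (T_ != length(stateseq$state)) stop_invalid("frame clock mismatch")
  if (n_shuffles < 1L) stop_invalid("n_shuffles must be >= 1")
  st <- stateseq$state
  inc <- stateseq$included
  occ <- tabulate(st[inc], stateseq$M)
  n_inc <- sum(inc)
  if (n_inc < 1L) stop_invalid("no included frames")
  act <- which(row == 1L)
  actual <- stat_from_active_idx(act, st, inc, occ, n_inc, statistic)
  p <- if (statistic == "mi") 1L else stateseq$M
  surrogates <- matrix(NA_real_, n_shuffles, p)
  shifts <- with_seed_(seed, sample.int(T_ - 1L, n_shuffles, replace = TRUE))
  for (s in seq_len(n_shuffles)) {
    rot <- (act - 1L + shifts[s]) %% T_ + 1L
    surrogates[s, ] <- stat_from_active_idx(rot, st, inc, occ, n_inc, statistic)
  }
  structure(list(statistic_name = statistic, actual = actual,
                 surrogates = surrogates, shifts = shifts, M = stateseq$M),
            class = "shuffle_distribution")
}

#' @export
print.shuffle_distribution <- function(x, ...) {
  cat(sprintf("<shuffle_distribution> %s, %d surrogates x %d value(s)\n",
              x$statistic_name, nrow(x$surrogates), ncol(x$surrogates)))
  invisible(x)
}

#' Empirical p-value against a surrogate distribution
#'
#' `p = #(surrogate > actual) / n_shuffles` per element (`tie_mode =
#' "strict"`, the default) or with `>=` (`"inclusive"`). The strict rule
#' can return exactly 0 when the actual value exceeds every surrogate; the
#' inclusive rule is available because strict counting inflates
#' significance when surrogates tie the actual value (e.g. empty bins).
#'
#' @param actual statistic value(s) (length `p`).
#' @param surrogates `n x p` matrix of surrogate values.
#' @param tie_mode `"strict"` (`>`) or `"inclusive"` (`>=`).
#' @return numeric vector of p-values in `[0, 1]` (NA where the actual
#'   statistic is undefined).
#' @export
empirical_pvalue <- function(actual, surrogates, tie_mode = c("strict", "inclusive")) {
  tie_mode <- match.arg(tie_mode)
  surrogates <- as.matrix(surrogates)
  if (ncol(surrogates) != length(actual)) {
    stop_invalid("surrogates must have one column per element of `actual`")
  }
  n <- nrow(surrogates)
  vapply(seq_along(actual), function(i) {
    if (is.na(actual[i])) return(NA_real_)
    cmp <- if (tie_mode == "strict") surrogates[, i] > actual[i]
           else surrogates[, i] >= actual[i]
    sum(cmp, na.rm = TRUE) / n
  }, numeric(1))
}

#' Mask non-significant entries of a tuning curve
#'
#' Entries whose p-value is at or above `alpha` are replaced by `NA`,
#' retaining only the significant part of a place field for display or
#' further analysis.
#'
#' @param likelihood tuning curve values (length `M`).
#' @param p_values aligned p-values.
#' @param alpha significance threshold in (0, 1), default 0.05.
#' @return the thresholded curve.
#' @export
threshold_field <- function(likelihood, p_values, alpha = 0.05) {
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  if (length(likelihood) != length(p_values)) {
    stop_invalid("likelihood and p_values must be aligned")
  }
  likelihood[is.na(p_values) | p_values >= alpha] <- NA_real_
  likelihood
}

#' Summarize a shuffle distribution into a significance result
#'
#' Convenience wrapper: per-element empirical p-values, the across-surrogate
#' mean/SD/SEM, and (for likelihood curves) the alpha-thresholded curve.
#'
#' @param dist a [circular_shuffle_statistic()] result.
#' @param alpha significance threshold.
#' @param tie_mode see [empirical_pvalue()].
#' @return An object of class `significance_result`.
#' @export
significance_from_shuffles <- function(dist, alpha = 0.05,
                                       tie_mode = c("strict", "inclusive")) {
  stopifnot(inherits(dist, "shuffle_distribution"))
  tie_mode <- match.arg(tie_mode)
  p <- empirical_pvalue(dist$actual, dist$surrogates, tie_mode)
  n <- nrow(dist$surrogates)
  m <- colMeans(dist$surrogates, na.rm = TRUE)
  sdv <- apply(dist$surrogates, 2L, stats::sd, na.rm = TRUE)
  thresholded <- if (dist$statistic_name == "likelihood_curve") {
    threshold_field(dist$actual, p, alpha)
  } else NULL
  structure(list(statistic_name = dist$statistic_name, actual = dist$actual,
                 p_value = p, shuffled_mean = m, shuffled_sd = sdv,
                 shuffled_sem = sdv / sqrt(n),
                 thresholded_likelihood = thresholded, alpha = alpha,
                 tie_mode = tie_mode, n_shuffles = n),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("<significance_result> %s, %d surrogates, alpha = %g\n",
              x$statistic_name, x$n_shuffles, x$alpha))
  if (x$statistic_name == "mi") {
    cat(sprintf("  actual MI = %.4g bits, p = %.3g\n", x$actual, x$p_value))
  } else {
    cat(sprintf("  %d/%d significant states\n",
                sum(x$p_value < x$alpha, na.rm = TRUE), length(x$p_value)))
  }
  invisible(x)
}

#' Bootstrap confidence intervals for a tuning statistic
#'
#' Each bootstrap sample draws `round(sample_fraction * n_included)`
#' included frames *with replacement* and recomputes the statistic; the
#' confidence band is the percentile interval per element. The default
#' (1000 samples on 50% of the data) follows the package's convention for
#' display bands; for calibrated coverage of the underlying per-state
#' probabilities use `sample_fraction = 1` (the canonical n-out-of-n
#' bootstrap — subsampling at 0.5 widens the band and over-covers).
#'
#' @inheritParams circular_shuffle_statistic
#' @param n_boot number of bootstrap samples.
#' @param sample_fraction fraction of included frames per sample, in (0, 1].
#' @param level confidence level in percent, in (0, 100).
#' @return An object of class `bootstrap_result`: `samples`
#'   (`n_boot` x `M` or 1), `ci_lower`, `ci_upper`, `level`,
#'   `sample_fraction`, `statistic_name`.
#' @export
bootstrap_ci <- function(raster_row, stateseq, n_boot = 1000,
                         sample_fraction = 0.5, level = 95, seed = NULL,
                         statistic = c("likelihood_curve", "mi")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(stateseq, "state_sequence"))
  check_scalar_number(sample_fraction, "sample_fraction", lower = 0, upper = 1,
                      strict_lower = TRUE)
  check_scalar_number(level, "level", lower = 0, upper = 100,
                      strict_lower = TRUE, strict_upper = TRUE)
  row <- as.integer(raster_row)
  if (length(row) != length(stateseq$state)) stop_invalid("frame clock mismatch")
  inc_idx <- which(stateseq$included)
  n_inc <- length(inc_idx)
  if (n_inc < 1L) stop_invalid("no included frames")
  n_s <- max(1L, round(sample_fraction * n_inc))
  M <- stateseq$M
  st_inc <- stateseq$state[inc_idx]
  a_inc <- row[inc_idx]
  p <- if (statistic == "mi") 1L else M
  samples <- matrix(NA_real_, n_boot, p)
  with_seed_(seed, {
    chunk <- max(1L, min(n_boot, floor(2e6 / n_s)))
    done <- 0L
    while (done < n_boot) {
      nb <- min(chunk, n_boot - done)
      pick <- sample.int(n_inc, n_s * nb, replace = TRUE)
      boot_col <- rep(seq_len(nb), each = n_s)
      comb <- st_inc[pick] + M * (boot_col - 1L)
      occ_b <- matrix(tabulate(comb, M * nb), M, nb)
      act_b <- matrix(tabulate(comb[a_inc[pick] == 1L], M * nb), M, nb)
      if (statistic == "likelihood_curve") {
        lik <- ifelse(occ_b > 0, act_b / occ_b, NA_real_)
        samples[done + seq_len(nb), ] <- t(lik)
      } else {
        for (b in seq_len(nb)) {
          samples[done + b, 1L] <- mi_from_counts(act_b[, b], occ_b[, b], n_s)
        }
      }
      done <- done + nb
    }
  })
  qs <- c((100 - level) / 200, 1 - (100 - level) / 200)
  ci <- apply(samples, 2L, function(v) {
    if (all(is.na(v))) return(c(NA_real_, NA_real_))
    stats::quantile(v, qs, na.rm = TRUE, names = FALSE)
  })
  structure(list(samples = samples, ci_lower = ci[1L, ], ci_upper = ci[2L, ],
                 level = level, sample_fraction = sample_fraction,
                 statistic_name = statistic, n_boot = n_boot),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %s, %d samples at %.0f%% of frames, %g%% CI\n",
              x$statistic_name, x$n_boot, 100 * x$sample_fraction, x$level))
  invisible(x)
}
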