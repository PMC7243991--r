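# Naive Bayes decoder: construction, log-domain equivalence with the
# linear-space oracle, prior/bias modes, MAP, metrics, epoch splitting,
# and the sweep harness.

uniform_model <- function(likelihood, marginal, prior_mode = "uniform",
                          variant = "log_product") {
  M <- ncol(likelihood)
  geometry <- data.frame(state = seq_len(M), x = (seq_len(M) - 0.5) * 3,
                         width = 3)
  decoder_model(likelihood, marginal, rep(1 / M, M), prior_mode, variant,
                geometry = geometry, sampling_rate = 30)
}

test_that("build_decoder wraps the tuning counts and validates neurons", {
  st <- toy_states(rep(1:2, each = 5), 2)
  raster <- binary_raster(rbind(c(1, 1, 0, 0, 0, 0, 0, 0, 0, 1),
                                rep(0, 10)), 30, "rise")
  expect_warning(m <- build_decoder(raster, st), "never active")
  expect_equal(as.numeric(m$likelihood), c(0.4, 0.2))
  expect_equal(m$marginal, 0.3)
  expect_identical(m$N, 1L)
  silent <- binary_raster(matrix(0, 2, 10), 30, "rise")
  expect_error(build_decoder(silent, st), "no neuron")
  # uniform prior scoring uses 1/M for every state
  eff <- caldecode:::decoder_effective_terms(m)
  expect_equal(eff$prior, rep(0.5, 2))
})

test_that("single one-hot neuron decodes its state; silence returns the prior", {
  lik <- rbind(c(1, 0, 0))
  m <- uniform_model(lik, marginal = 0.2)
  raster <- binary_raster(rbind(c(1, 0)), 30, "rise")
  traj <- decode_posteriors(raster, m)
  expect_equal(traj$posteriors[1, ], c(1, 0, 0))
  expect_identical(traj$map_state[1], 1L)
  # frame 2: no active neuron -> posterior = prior, flagged undecodable
  expect_equal(traj$posteriors[2, ], rep(1 / 3, 3))
  expect_true(is.na(traj$map_state[2]))
  expect_false(traj$decodable[2])
})

test_that("log-domain MAP equals the brute-force linear product", {
  withr::with_seed(1234, {
    for (i in 1:200) {
      N <- sample(1:8, 1); M <- sample(2:12, 1)
      lik <- matrix(runif(N * M, 0.01, 1), N, M)   # strictly positive
      marg <- runif(N, 0.05, 0.8)
      prior <- runif(M, 0.1, 1); prior <- prior / sum(prior)
      active <- rbinom(N, 1, 0.6)
      if (!any(active == 1)) active[sample(N, 1)] <- 1L
      m <- decoder_model(lik, marg, prior, "observed", "log_product",
                         sampling_rate = 30)
      traj <- decode_posteriors(binary_raster(cbind(active), 30, "rise"), m)
      # oracle: direct product of P(A_k|S) P(S) / P(A_k) over active neurons
      direct <- prior^sum(active)
      for (k in which(active == 1)) direct <- direct * lik[k, ] / marg[k]
      expect_identical(traj$map_state[1],
                       as.integer(which.max(direct)))
      expect_equal(traj$posteriors[1, ], direct / sum(direct),
                   tolerance = 1e-9)
    }
  })
})

test_that("zero likelihood vetoes a state in the log_product variant", {
  lik <- rbind(c(0, 0.5, 0.5), c(0.5, 0.5, 0))
  m <- uniform_model(lik, c(0.3, 0.3))
  raster <- binary_raster(cbind(c(1, 1)), 30, "rise")
  traj <- decode_posteriors(raster, m)
  expect_equal(traj$posteriors[1, c(1, 3)], c(0, 0))
  expect_identical(traj$map_state[1], 2L)
})

test_that("unbiased mode is MAP-invariant under log_product but not log1p", {
  # removing the per-neuron bias shifts all log-product scores by a
  # frame-constant, so posteriors are untouched; the log1p transform mixes
  # the bias nonlinearly and can change the ranking
  withr::with_seed(77, {
    for (i in 1:25) {
      N <- sample(2:6, 1); M <- sample(3:10, 1)
      lik <- matrix(runif(N * M, 0.01, 1), N, M)
      marg <- runif(N, 0.02, 0.9)
      active <- cbind(rbinom(N, 1, 0.7))
      raster <- binary_raster(active, 30, "rise")
      t_biased <- decode_posteriors(raster, uniform_model(lik, marg))
      t_unbiased <- decode_posteriors(raster,
                                      uniform_model(lik, marg,
                                                    prior_mode = "unbiased"))
      expect_equal(t_biased$posteriors, t_unbiased$posteriors,
                   tolerance = 1e-9)
    }
  })
  # constructed instance where log1p scoring flips the MAP once the bias
  # is removed: a tiny-marginal neuron dominates only when divided by it
  lik <- rbind(c(0.9, 0.01), c(0.01, 0.99))
  marg <- c(0.01, 0.5)
  raster <- binary_raster(cbind(c(1, 1)), 30, "rise")
  map_b <- decode_posteriors(raster, uniform_model(lik, marg,
                                                   variant = "log1p"))$map_state
  map_u <- decode_posteriors(raster,
                             uniform_model(lik, marg, prior_mode = "unbiased",
                                           variant = "log1p"))$map_state
  expect_identical(map_b, 1L)
  expect_identical(map_u, 2L)
})

test_that("MAP takes the argmax with deterministic tie-breaks", {
  expect_identical(map_estimate(rbind(c(0.1, 0.7, 0.2))), 2L)
  expect_identical(map_estimate(rbind(c(0.5, 0.5))), 1L)
  P <- matrix(runif(15), 5, 3)
  expect_length(map_estimate(P), 5)
  expect_identical(map_estimate(rbind(c(NA, NA))), NA_integer_)
})

test_that("agreement and error metrics are exact on known vectors", {
  expect_equal(decoding_agreement(c(1, 2, 3, 4), c(1, 2, 4, 3)), 0.5)
  expect_equal(decoding_agreement(1:5, 1:5), 1)
  expect_equal(decoding_agreement(c(2, 3, 4), c(1, 2, 3)), 0)  # always one off
  expect_error(decoding_agreement(NA_integer_, 1L), "decodable")
  geo1 <- data.frame(state = 1:34, x = (1:34 - 0.5) * 3)
  err <- decoding_error(c(22L, 22L), c(22L, 20L), geo1)
  expect_equal(err$per_frame_cm, c(0, 6))        # centers 64.5 vs 58.5
  geo2 <- data.frame(state = 1:2, x = c(1.5, 4.5), y = c(1.5, 5.5))
  e2 <- decoding_error(1L, 2L, geo2)             # 3-4-5 triangle on centers
  expect_equal(e2$per_frame_cm, 5)
  skip <- decoding_error(c(NA, 3L), c(1L, 3L), geo1)
  expect_identical(skip$n_skipped, 1L)
  expect_equal(skip$mean_cm, 0)
})

test_that("confusion matrix normalizes visited columns", {
  cm <- confusion_matrix(c(1L, 1L, 2L, 2L), c(1L, 1L, 1L, 2L), 3)
  expect_equal(colSums(cm[, attr(cm, "visited")]), c(1, 1), ignore_attr = TRUE)
  expect_equal(cm[1, 1], 2 / 3)
  expect_identical(attr(cm, "visited"), c(TRUE, TRUE, FALSE))
  perfect <- confusion_matrix(c(1L, 2L, 3L), c(1L, 2L, 3L), 3)
  expect_equal(perfect, diag(3), ignore_attr = TRUE)
  always1 <- confusion_matrix(rep(1L, 4), c(1L, 2L, 3L, 1L), 3)
  expect_equal(always1[1, ], rep(1, 3))
  expect_error(confusion_matrix(4L, 1L, 3), "range")
})

test_that("epoch splits are block-wise, disjoint, and reproducible", {
  inc <- rep(TRUE, 1000)
  sp <- split_epochs(1000, inc, 0.5, block_s = 5, rate = 30, n_trials = 5,
                     seed = 3)
  for (s in sp) {
    expect_false(any(s$train & s$test))
    expect_lte(abs(sum(s$train) - 500), 150)     # within one 150-frame block
    expect_equal(sum(s$train) + sum(s$test), 1000)
  }
  sp2 <- split_epochs(1000, inc, 0.5, 5, 30, 5, seed = 3)
  expect_identical(sp, sp2)
  # excluded frames belong to neither mask
  inc2 <- rep(c(TRUE, FALSE), 500)
  sp3 <- split_epochs(1000, inc2, 0.5, 5, 30, 1, seed = 4)[[1]]
  expect_false(any(sp3$train[!inc2] | sp3$test[!inc2]))
  expect_error(split_epochs(100, rep(TRUE, 100), 0.5, block_s = 10, rate = 30),
               "2 blocks")
  expect_error(split_epochs(1000, inc, 1.5), "train_fraction")
})

test_that("posterior rows sum to one and windows suppress jumps", {
  ses <- simulate_session(duration_s = 240, n_cells = 40, seed = 90)
  st <- session_states(ses)
  raster <- binarize_from_deconvolved(ses$spikes, 30)
  sp <- split_epochs(ncol(raster$states), st$included, 0.5, 5, 30, 1, 5)[[1]]
  m <- build_decoder(raster, restrict_states(st, sp$train))
  t0 <- decode_posteriors(raster, m, 0)
  expect_true(all(abs(rowSums(t0$posteriors) - 1) < 1e-9))
  t5 <- decode_posteriors(raster, m, 0.5)
  expect_true(all(abs(rowSums(t5$posteriors) - 1) < 1e-9))
  jumps <- function(traj) {
    x <- st$geometry$x[traj$map_state]
    mean(abs(diff(x)) > 20, na.rm = TRUE)
  }
  expect_lt(jumps(t5), jumps(t0))
  # the causal window variant decodes too, just with a lag
  tp <- decode_posteriors(raster, m, 0.5, window_mode = "past")
  expect_true(all(abs(rowSums(tp$posteriors) - 1) < 1e-9))
})

test_that("run_sweep produces a tidy grid x trial table", {
  ses <- simulate_session(duration_s = 180, n_cells = 20, seed = 91)
  st <- session_states(ses)
  raster <- binarize_from_deconvolved(ses$spikes, 30)
  out <- run_sweep(raster, st, list(window_s = c(0, 0.5)), n_trials = 3,
                   seed = 2)
  expect_identical(nrow(out), 6L)
  expect_identical(unique(out$parameter), "window_s")
  expect_true(all(c("agreement", "mean_error_cm") %in% names(out)))
  expect_error(run_sweep(raster, st, list()), "grid")
  expect_error(run_sweep(raster, st, list(bogus = 1)), "grid")
  # same seed, same table
  out2 <- run_sweep(raster, st, list(window_s = c(0, 0.5)), n_trials = 3,
                    seed = 2)
  expect_identical(out, out2)
})
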