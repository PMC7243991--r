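# Tuning estimation: worked counting examples, Bayes consistency, mutual
# information identities, smoothing, and noise injection.

worked_model <- function(included = NULL) {
  # S = [1 1 1 1 1 2 2 2 2 2], A = [1 1 0 0 0 0 0 0 0 1]
  st <- toy_states(rep(1:2, each = 5), 2, included = included)
  estimate_tuning(toy_raster(c(1, 1, 0, 0, 0, 0, 0, 0, 0, 1)), st)
}

test_that("probabilities are exact frame counts", {
  tun <- worked_model()
  expect_equal(tun$marginal, 0.3)
  expect_equal(tun$prior, c(0.5, 0.5))
  expect_equal(as.numeric(tun$joint_active), c(0.2, 0.1))
  expect_equal(as.numeric(tun$likelihood), c(0.4, 0.2))
  # internal consistency: likelihood * prior = joint; joint sums to marginal
  expect_equal(as.numeric(tun$likelihood) * tun$prior,
               as.numeric(tun$joint_active))
  expect_equal(sum(tun$joint_active), tun$marginal)
  expect_equal(sum(tun$joint_active) + sum(tun$joint_inactive), 1)
})

test_that("exclusion masks restrict the counting", {
  tun <- worked_model(included = c(rep(FALSE, 5), rep(TRUE, 5)))
  expect_equal(tun$prior, c(0, 1))
  expect_true(is.na(tun$likelihood[1, 1]))      # unvisited state: undefined
  expect_equal(tun$likelihood[1, 2], 0.2)
  expect_error(worked_model(included = rep(FALSE, 10)), "included")
})

test_that("always-active neurons have unit likelihood in every visited state", {
  st <- toy_states(rep(1:3, 4), 3)
  tun <- estimate_tuning(toy_raster(rep(1, 12)), st)
  expect_equal(as.numeric(tun$likelihood), rep(1, 3))
})

test_that("posterior follows Bayes' rule and sums to one", {
  tun <- worked_model()
  post <- posterior_from_tuning(tun)
  expect_equal(as.numeric(post), c(2/3, 1/3))
  # flat likelihood: posterior equals the prior
  st <- toy_states(rep(1:2, each = 4), 2)
  flat <- estimate_tuning(toy_raster(c(1, 0, 0, 0, 1, 0, 0, 0)), st)
  expect_equal(as.numeric(posterior_from_tuning(flat)), flat$prior)
  # never-active neuron: NA posterior plus a warning
  silent <- estimate_tuning(toy_raster(rep(0, 8)), st)
  expect_warning(p0 <- posterior_from_tuning(silent), "never active")
  expect_true(all(is.na(p0)))
})

test_that("MI equals the entropy identity and its landmark values", {
  # independence: joint = outer product -> MI = 0
  st <- toy_states(rep(1:2, 6), 2)
  indep <- estimate_tuning(toy_raster(rep(c(1, 1, 0, 0), 3)), st)
  expect_equal(indep$mi, 0, tolerance = 1e-12)
  # perfectly informative neuron over two equiprobable states -> 1 bit
  perfect <- estimate_tuning(toy_raster(rep(c(1, 0), 6)), st)
  expect_equal(perfect$mi, 1, tolerance = 1e-12)
  # random joint tables: MI = H(S) + H(A) - H(S,A)
  withr::with_seed(99, {
    for (i in 1:25) {
      M <- sample(2:12, 1)
      joint <- matrix(runif(2 * M), 2)
      joint <- joint / sum(joint)
      model <- structure(list(
        marginal = sum(joint[1, ]), prior = colSums(joint),
        joint_active = joint[1, , drop = FALSE],
        joint_inactive = joint[2, , drop = FALSE],
        occupancy = rep(1L, M), n_neurons = 1L, M = M), class = "tuning_model")
      H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
      expect_equal(mutual_info(model),
                   H(colSums(joint)) + H(rowSums(joint)) - H(as.numeric(joint)),
                   tolerance = 1e-12)
    }
  })
})

test_that("MI ranks neurons by tuning contrast", {
  tk <- simulate_behavior_1d(300, 30, 100, seed = 31)
  p_max <- seq(0.02, 0.4, length.out = 60)      # rising field contrast
  pc <- simulate_place_cells(tk, 60, p_max = p_max, baseline = 0.01, seed = 32)
  st <- exclude_immobility(discretize_1d(tk), compute_speed(tk), 5)
  tun <- estimate_tuning(binarize_from_deconvolved(pc$spikes, 30), st)
  rho <- cor(tun$mi, p_max / 0.01, method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("Gaussian smoothing preserves mass, fixpoints, and undefined bins", {
  tun <- worked_model()
  expect_identical(smooth_tuning(tun, 0), tun)
  st <- toy_states(rep(1:30, each = 2), 30)
  act <- as.integer(rep(1:30, each = 2) == 15)
  delta <- estimate_tuning(toy_raster(act), st)
  sm <- smooth_tuning(delta, 1.5)   # interior delta: kernel support stays in-grid
  expect_equal(sum(sm$likelihood), sum(delta$likelihood), tolerance = 1e-9)
  # constant curve is a convolution fixed point
  flat <- estimate_tuning(toy_raster(rep(1, 60)), st)
  expect_equal(smooth_tuning(flat, 2)$likelihood, flat$likelihood)
  # undefined states stay undefined and are excluded from the kernel
  stm <- toy_states(c(rep(1L, 5), rep(3L, 5)), 3)
  holey <- estimate_tuning(toy_raster(c(rep(1, 5), rep(0, 5))), stm)
  smh <- smooth_tuning(holey, 1)
  expect_true(is.na(smh$likelihood[1, 2]))
  expect_false(anyNA(smh$likelihood[1, c(1, 3)]))
  expect_error(smooth_tuning(tun, -1), "sigma")
})

test_that("2D smoothing keeps a delta map's mass on the grid", {
  tk <- simulate_behavior_2d(900, 30, c(45, 45), 20, seed = 41)
  st <- discretize_2d(tk, 3)
  # neuron active only in one interior state
  target <- st$geometry$state[st$geometry$x == 22.5 & st$geometry$y == 22.5]
  act <- as.integer(st$state == target)
  tun <- estimate_tuning(toy_raster(act), st)
  # sigma chosen so the truncated kernel support stays off the walls,
  # where renormalization would trade a little mass
  sm <- smooth_tuning(tun, 0.75)
  expect_equal(sum(sm$likelihood, na.rm = TRUE),
               sum(tun$likelihood, na.rm = TRUE), tolerance = 1e-9)
  expect_false(anyNA(sm$likelihood[, tun$occupancy > 0]))
})

test_that("noise injection replaces exactly the requested entry count", {
  ses <- tiny_session(seed = 51, duration_s = 120)
  st <- discretize_1d(ses$track)   # no exclusions: every bin visited
  tun <- estimate_tuning(binarize_from_deconvolved(ses$spikes, 30), st)
  expect_identical(inject_noise(tun, 0), tun)
  noisy <- inject_noise(tun, 0.5, seed = 1)
  n_diff <- rowSums(noisy$likelihood != tun$likelihood, na.rm = TRUE)
  expect_true(all(n_diff == round(0.5 * tun$M)))
  full <- inject_noise(tun, 1, seed = 2)
  defined <- rowSums(!is.na(tun$likelihood))
  expect_equal(rowSums(full$likelihood != tun$likelihood, na.rm = TRUE),
               defined, ignore_attr = TRUE)
  expect_error(inject_noise(tun, 1.2), "fraction")
  # reproducible
  expect_identical(inject_noise(tun, 0.3, seed = 9)$likelihood,
                   inject_noise(tun, 0.3, seed = 9)$likelihood)
})

test_that("MI is bounded by the marginal entropies", {
  ses <- tiny_session(seed = 61, duration_s = 60)
  st <- session_states(ses)
  tun <- estimate_tuning(binarize_from_deconvolved(ses$spikes, 30), st)
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  HS <- H(tun$prior)
  for (k in seq_len(tun$n_neurons)) {
    HA <- H(c(tun$marginal[k], 1 - tun$marginal[k]))
    expect_gte(tun$mi[k], 0)
    expect_lte(tun$mi[k], min(HS, HA) + 1e-12)
  }
})
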