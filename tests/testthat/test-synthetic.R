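# Synthetic session generator: frame accounting, bounds, trajectory
# statistics, transient kinetics, and determinism.

test_that("1D behavior respects the frame clock and track bounds", {
  tk <- simulate_behavior_1d(900, 30, 100, seed = 1)
  expect_length(tk$timestamps, 27000)           # duration x rate
  expect_true(all(tk$position >= 0 & tk$position <= 100))
  expect_error(simulate_behavior_1d(-5, 30, 100), "duration")
  expect_error(simulate_behavior_1d(10, 0, 100), "sampling_rate")
})

test_that("pause-free running yields the expected lap count", {
  # 900 s at 20 cm/s covers 18000 cm; a full lap is 200 cm -> ~90 laps
  tk <- simulate_behavior_1d(900, 30, 100, mean_speed_cms = 20,
                             pause_prob = 0, seed = 7)
  d <- diff(tk$position[, 1])
  d <- d[d != 0]
  reversals <- sum(diff(sign(d)) != 0)
  laps <- reversals / 2
  expect_gt(laps, 0.8 * 90)
  expect_lt(laps, 1.2 * 90)
})

test_that("2D walk stays in the arena, stops at zero speed, covers all bins", {
  tk <- simulate_behavior_2d(900, 30, c(45, 45), 20, seed = 3)
  expect_true(all(tk$position >= 0 & tk$position <= 45))
  frozen <- simulate_behavior_2d(10, 30, c(45, 45), 0, seed = 3)
  expect_true(all(frozen$position == frozen$position[1, 1]))
  bins <- pmin(floor(tk$position[, 1] / 3), 14) * 15 +
    pmin(floor(tk$position[, 2] / 3), 14)
  expect_length(unique(bins), 225)              # every 3x3 cm bin visited
})

test_that("place-cell emission follows the Gaussian field model", {
  tk <- simulate_behavior_1d(300, 30, 100, seed = 2)
  expect_error(simulate_place_cells(tk, 5, p_max = 0.1, baseline = 0.2),
               "baseline")
  # p_max == baseline is rejected; near-flat rate gives state-independent activity
  pc <- simulate_place_cells(tk, 3, p_max = 0.2, baseline = 0.2 - 1e-9, seed = 4)
  st <- discretize_1d(tk)
  tun <- estimate_tuning(binarize_from_deconvolved(pc$spikes, 30), st)
  expect_lt(max(tun$mi), 0.01)
  # Bernoulli rate check at the field center of a non-directional cell
  tk0 <- behavior_track(seq(0, 4000 - 1/30, by = 1/30),
                        rep(50, 120000), 100)
  pc0 <- simulate_place_cells(tk0, 1, field_width_cm = 5, p_max = 0.25,
                              baseline = 0.01, jitter_cm = 0, seed = 9)
  stopifnot(abs(pc0$ground_truth$center_x - 50) < 1e-9)
  rate_hat <- mean(pc0$spikes)
  se <- sqrt(0.25 * 0.75 / 120000)
  expect_lt(abs(rate_hat - 0.25), 3 * se)       # frame at center -> P = p_max
})

test_that("field centers tile the arena and are recovered from activity", {
  ses <- simulate_session(duration_s = 300, n_cells = 30, p_max = 0.3, seed = 5)
  st <- session_states(ses)
  tun <- estimate_tuning(binarize_from_deconvolved(ses$spikes, 30), st)
  peaks <- apply(tun$likelihood, 1, which.max)
  true_bins <- floor(ses$ground_truth$center_x / 3) + 1
  expect_gte(mean(abs(peaks - true_bins) <= 1), 0.9)
})

test_that("calcium synthesis has the closed-form kernel peak and is linear", {
  expect_error(synthesize_calcium(matrix(1, 1, 10), 30, tau_rise_s = 1,
                                  tau_decay_s = 0.5), "tau")
  zero <- synthesize_calcium(matrix(0, 2, 50), 30, noise_sd = 0)
  expect_true(all(zero$values == 0))
  # single event: peak at the double-exponential maximum, within one frame
  spk <- matrix(0, 1, 300); spk[1, 100] <- 1
  tr <- synthesize_calcium(spk, 30, 0.1, 1.0, noise_sd = 0)
  peak_lag <- which.max(tr$values[1, ]) - 100
  expect_lt(abs(peak_lag - calcium_kernel_peak_s(0.1, 1.0) * 30), 1)
  # two events 10 tau_decay apart: equal peaks within 1%
  spk2 <- matrix(0, 1, 700); spk2[1, c(50, 50 + 300)] <- 1
  tr2 <- synthesize_calcium(spk2, 30, 0.1, 1.0, noise_sd = 0)
  p1 <- max(tr2$values[1, 1:340]); p2 <- max(tr2$values[1, 341:700])
  expect_lt(abs(p2 - p1) / p1, 0.01)
  # linearity in events at zero noise
  sa <- matrix(rbinom(200, 1, 0.05), 1); sb <- matrix(rbinom(200, 1, 0.05), 1)
  ta <- synthesize_calcium(sa, 30, noise_sd = 0)$values
  tb <- synthesize_calcium(sb, 30, noise_sd = 0)$values
  tab <- synthesize_calcium(sa + sb, 30, noise_sd = 0)$values
  expect_equal(tab, ta + tb, tolerance = 1e-10)
})

test_that("a fixed seed reproduces the whole session bit-identically", {
  s1 <- tiny_session(seed = 77, duration_s = 30)
  s2 <- tiny_session(seed = 77, duration_s = 30)
  expect_identical(s1$track$position, s2$track$position)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$traces$values, s2$traces$values)
  expect_identical(s1$ground_truth, s2$ground_truth)
})

test_that("directional cells fire at field rate only in the preferred direction", {
  tk <- simulate_behavior_1d(600, 30, 100, pause_prob = 0, seed = 11)
  pc <- simulate_place_cells(tk, 20, p_max = 0.3, frac_directional = 1,
                             seed = 12)
  expect_true(all(pc$ground_truth$direction_pref %in% c("left", "right")))
  st <- discretize_1d(tk)
  std <- augment_direction(st, tk)
  std <- exclude_immobility(std, compute_speed(tk), 5)
  cmp <- compare_state_refinements(binarize_from_deconvolved(pc$spikes, 30),
                                   exclude_immobility(st, compute_speed(tk), 5),
                                   std)
  # direction refinement should raise the population's peak likelihoods
  expect_gt(median(cmp$peak_likelihood_refined - cmp$peak_likelihood_base), 0)
})
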