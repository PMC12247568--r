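test_that("state sequences follow the Markov dwell process", {
  # K = 1 is constant
  one <- simulate_state_sequence(synthetic_spec(k_states = 1, duration_s = 5))
  expect_true(all(one$sample_labels == 1L))

  # symmetric chain long-run coverage approaches 1/K
  spec <- synthetic_spec(duration_s = 1000, seed = 31)
  seq_ <- simulate_state_sequence(spec)
  cover <- tabulate(seq_$step_labels, 4) / length(seq_$step_labels)
  expect_true(all(abs(cover - 0.25) < 0.05))

  # geometric dwell with the requested mean (600 ms at 100 ms steps)
  r <- rle(seq_$step_labels)
  expect_lt(abs(mean(r$lengths) - 6) / 6, 0.1)

  # the expanded labels are derivable from the step labels
  expect_equal(length(seq_$sample_labels), 1000 * 128)
})

test_that("generation is fully seed-determined", {
  spec <- synthetic_spec(duration_s = 10, seed = 32)
  a <- simulate_parcel_phases(spec)
  b <- simulate_parcel_phases(spec)
  expect_identical(a$ts$data, b$ts$data)
  expect_identical(a$ground_truth$sample_labels,
                   b$ground_truth$sample_labels)
  c_ <- simulate_parcel_phases(synthetic_spec(duration_s = 10, seed = 33))
  expect_false(identical(a$ts$data, c_$ts$data))
})

test_that("planted edges out-synchronise non-edges through the full pipeline", {
  spec <- synthetic_spec(duration_s = 100, seed = 34)
  sim <- simulate_parcel_phases(spec)
  pt <- morlet_phase(sim$ts)
  cs <- sliding_ciplv(pt)
  cent <- sim$ground_truth$planted_centroids
  wl <- window_truth_labels(sim$ground_truth$sample_labels,
                            cs$window_starts, cs$t_win, 4)
  sep <- sapply(1:4, function(s) {
    w <- which(wl == s)
    mean(cs$values[w, cent[s, ] == 1]) - mean(cs$values[w, cent[s, ] == 0])
  })
  expect_true(all(sep >= 0.25))
  expect_gte(mean(sep), 0.3)
})

test_that("near-noiseless locking saturates planted-edge ciPLV", {
  spec <- synthetic_spec(duration_s = 30, k_states = 1,
                         phase_noise_kappa = 1e5, background_snr = 1e6,
                         mean_dwell_ms = 1e9, seed = 35)
  sim <- simulate_parcel_phases(spec)
  pt <- morlet_phase(sim$ts)
  cs <- sliding_ciplv(pt)
  cent <- planted_centroids(spec)
  expect_gt(mean(cs$values[, cent[1, ] == 1]), 0.97)
})

test_that("sensor-map simulation honours labels, noise, and CAR", {
  labels <- rep(1, 100)
  sim <- simulate_sensor_maps(3, 10, labels, noise_sd = 0, seed = 36)
  expect_lt(max(abs(colMeans(sim$rec$data))), 1e-9)
  fitted <- fit_microstates(sim$rec, k = 1, n_init = 2, seed = 1)
  expect_gt(abs(sum(fitted$maps[1, ] * sim$maps[1, ])), 0.999)
  cov <- state_coverage(backfit_microstates(
    sim$rec, structure(list(maps = sim$maps, k = 3L,
                            channel_labels = sim$rec$channel_labels),
                       class = "microstate_model"))$labels, k = 3)
  expect_equal(cov$coverage, c(100, 0, 0))
})

test_that("invalid synthetic specs are rejected", {
  expect_error(
    synthetic_spec(n_parcels = 6,
                   state_edge_sets = list(cbind(1, 9)),
                   state_offsets = list(rep(0, 6)), k_states = 1),
    class = "ps_invalid_spec")
  spec <- synthetic_spec(duration_s = 2)
  expect_error(simulate_parcel_phases(spec, labels = rep(1L, 5)),
               class = "ps_invalid_spec")
})
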