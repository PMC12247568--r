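test_that("ciPLV matches its closed forms on constant-lag windows", {
  expect_equal(ciplv_window(rep(pi / 2, 38)), 1)
  expect_equal(ciplv_window(rep(-pi / 2, 38)), 1)
  expect_equal(ciplv_window(rep(0, 38)), 0)      # zero-lag suppressed
  expect_equal(ciplv_window(c(0, 0, pi / 2, pi / 2)),
               0.5 / sqrt(1 - 0.25), tolerance = 1e-9)
  expect_error(ciplv_window(pi / 2), class = "ps_window_too_short")
  expect_error(ciplv_window(c(0, NaN)), class = "ps_invalid_input")
})

test_that("ciPLV is invariant to common phase shifts and lag sign", {
  set.seed(6)
  for (i in 1:20) {
    d <- runif(38, -pi, pi)
    base <- ciplv_window(d)
    expect_equal(ciplv_window(d + 0.7), ciplv_window((d + 0.7)), # same series
                 tolerance = 0)
    expect_equal(ciplv_window(-d), base, tolerance = 1e-12)
  }
  # common shift of both phase series leaves the difference unchanged by
  # construction; the signed variant flips with the lag sign
  d <- rep(pi / 3, 38)
  expect_equal(ciplv_window(d, signed = TRUE),
               -ciplv_window(-d, signed = TRUE), tolerance = 1e-12)
})

test_that("the uniform-phase null shrinks with window length and centers at zero", {
  set.seed(7)
  n_win <- 4000
  m38 <- replicate(n_win, ciplv_window(runif(38, 0, 2 * pi), signed = TRUE))
  se <- sd(m38) / sqrt(n_win)
  expect_lt(abs(mean(m38)), 3 * se)
  mag <- sapply(c(38, 152, 608), function(T) {
    mean(replicate(1000, ciplv_window(runif(T, 0, 2 * pi))))
  })
  expect_true(all(diff(mag) < 0))
})

test_that("sliding windows follow the stated arithmetic and lock detection", {
  # 300 s at 128 Hz with a 300/100 ms scheme gives 2998 windows of T = 38
  srate <- 128
  n <- srate * 300
  fake <- structure(list(
    phases = array(runif(2 * 1 * n, -pi, pi), c(2, 1, n)),
    amplitudes = array(1, c(2, 1, n)), freqs = 10, srate = srate,
    valid = rep(TRUE, n), parcel_labels = c("a", "b")),
    class = "phase_tensor")
  spec <- sliding_window_spec(300, 100)
  cs <- sliding_ciplv(fake, spec)
  expect_equal(cs$t_win, 38)
  expect_equal(nrow(cs$values), 2998)
  expect_equal(cs$window_starts[1:3], c(0, 13, 26)) # round(k * 12.8)

  # two parcels locked at pi/2 at every grid frequency stay at ciPLV ~ 1
  srate <- 128
  tt <- seq_len(srate * 20) / srate
  base <- 2 * pi * 10 * tt
  pt <- structure(list(
    phases = array(0, c(2, 3, length(tt))),
    amplitudes = array(1, c(2, 3, length(tt))),
    freqs = c(9, 10, 11), srate = srate, valid = rep(TRUE, length(tt)),
    parcel_labels = c("a", "b")), class = "phase_tensor")
  for (f in 1:3) {
    pt$phases[1, f, ] <- wrap_phase_for_test(base)
    pt$phases[2, f, ] <- wrap_phase_for_test(base - pi / 2)
  }
  locked <- sliding_ciplv(pt)
  expect_true(all(locked$values[, 1] > 0.999))

  # windows overlapping invalid samples are dropped
  pt$valid[1000:1020] <- FALSE
  dropped <- sliding_ciplv(pt)
  expect_lt(nrow(dropped$values), nrow(locked$values))
  bad_hit <- vapply(dropped$window_starts, function(s)
    any(!pt$valid[(s + 1):(s + dropped$t_win)]), logical(1))
  expect_false(any(bad_hit))
})

test_that("proportional thresholding keeps exactly the strongest fraction", {
  # P = 150 gives 11175 pairs and exactly 1117 edges per window
  set.seed(8)
  p <- 150
  npair <- choose(p, 2)
  cs <- structure(list(
    values = matrix(runif(2 * npair), 2), pair_index = make_pair_index(p),
    window_starts = c(0L, 13L), t_win = 38L, step_ms = 100,
    srate = 128, parcel_labels = paste0("p", 1:p)), class = "conn_series")
  g <- threshold_top_fraction(cs, 0.10)
  expect_equal(g$n_keep, 1117L)
  expect_true(all(rowSums(g$edges) == 1117L))

  # brute-force check on 5 parcels / 10 pairs: only the single max survives
  cs5 <- structure(list(
    values = matrix(c(3, 9, 1, 4, 8, 2, 7, 5, 6, 0), 1),
    pair_index = make_pair_index(5), window_starts = 0L, t_win = 38L,
    step_ms = 100, srate = 128, parcel_labels = paste0("p", 1:5)),
    class = "conn_series")
  g5 <- threshold_top_fraction(cs5, 0.10)
  expect_equal(which(g5$edges[1, ]), 2L)

  # ties break toward the lower pair index
  cs_tie <- cs5
  cs_tie$values <- matrix(rep(1, 10), 1)
  g_tie <- threshold_top_fraction(cs_tie, 0.25)
  expect_equal(which(g_tie$edges[1, ]), 1:2)

  expect_error(threshold_top_fraction(cs5, 0.01),
               class = "ps_degenerate_threshold")
})

test_that("thresholded graphs are equivariant under parcel relabeling", {
  set.seed(9)
  p <- 20
  npair <- choose(p, 2)
  vals <- matrix(runif(3 * npair), 3)
  mk <- function(v) structure(list(
    values = v, pair_index = make_pair_index(p), window_starts = 0:2,
    t_win = 38L, step_ms = 100, srate = 128,
    parcel_labels = paste0("p", 1:p)), class = "conn_series")
  g1 <- threshold_top_fraction(mk(vals), 0.10)
  for (rep_ in 1:3) {
    perm <- sample(p)
    colmap <- pair_permutation(p, perm)
    inv <- match(seq_len(npair), colmap)
    g2 <- threshold_top_fraction(mk(vals[, inv, drop = FALSE]), 0.10)
    # relabeling parcels permutes the retained edge set identically
    expect_equal(g2$edges, g1$edges[, inv, drop = FALSE])
  }
})
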