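test_that("resampling preserves a pure sinusoid and the recording geometry", {
  srate <- 512
  t <- seq(0, 4 - 1 / srate, by = 1 / srate)
  x <- sin(2 * pi * 5 * t)
  rec <- eeg_recording(rbind(a = x, b = x), srate = srate)

  out <- resample_recording(rec, 128)
  expect_equal(out$srate, 128)
  expect_equal(ncol(out$data), length(t) / 4)

  t2 <- seq(0, by = 1 / 128, length.out = ncol(out$data))
  ref <- sin(2 * pi * 5 * t2)
  core <- 40:(length(ref) - 40)            # away from filter edges
  expect_gt(cor(out$data[1, core], ref[core]), 0.999)

  expect_identical(resample_recording(rec, srate), rec)
  expect_error(resample_recording(rec, 1024),
               class = "ps_upsampling_not_supported")
})

test_that("resampling in two hops matches one hop within filter tolerance", {
  srate <- 512
  set.seed(1)
  x <- as.vector(stats::filter(rnorm(2048), rep(0.2, 5), sides = 2))
  x[is.na(x)] <- 0
  rec <- eeg_recording(rbind(x), srate = srate)
  one <- resample_recording(rec, 128)
  two <- resample_recording(resample_recording(rec, 256), 128)
  core <- 60:(ncol(one$data) - 60)
  expect_gt(cor(one$data[1, core], two$data[1, core]), 0.999)
})

test_that("band-pass keeps in-band power, rejects out-of-band, at zero phase", {
  srate <- 128
  n <- srate * 20
  tt <- seq_len(n) / srate
  x <- sin(2 * pi * 0.2 * tt) + sin(2 * pi * 10 * tt)
  rec <- eeg_recording(rbind(x), srate = srate)
  out <- bandpass_fir(rec, 1, 40)

  bin_power <- function(sig, f) Mod(fft(sig))[round(f * n / srate) + 1]^2
  atten_02 <- 10 * log10(bin_power(x, 0.2) / bin_power(out$data[1, ], 0.2))
  change_10 <- 10 * log10(bin_power(x, 10) / bin_power(out$data[1, ], 10))
  expect_gt(atten_02, 20)
  expect_lt(abs(change_10), 1)

  # zero-phase: cross-correlation of a narrow-band filtered sinusoid peaks
  # at zero lag
  y <- sin(2 * pi * 10 * tt)
  fy <- bandpass_fir(eeg_recording(rbind(y), srate = srate), 8, 12)$data[1, ]
  cc <- stats::ccf(fy[200:(n - 200)], y[200:(n - 200)], lag.max = 3,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  zero <- bandpass_fir(eeg_recording(matrix(0, 1, n), srate = srate), 1, 40)
  expect_true(all(zero$data == 0))
  expect_error(bandpass_fir(rec, 1, 70), class = "ps_invalid_band")
})

test_that("common average referencing zeroes good-channel means and is idempotent", {
  expect_equal(
    rereference_car(eeg_recording(matrix(c(1, 3), 2, 1), srate = 1))$data[, 1],
    c(ch1 = -1, ch2 = 1))

  set.seed(2)
  rec <- eeg_recording(matrix(rnorm(64 * 50), 64), srate = 128)
  car <- rereference_car(rec)
  expect_lt(max(abs(colMeans(car$data))), 1e-10)
  expect_equal(car$reference, "CAR")
  twice <- rereference_car(car)
  expect_equal(twice$data, car$data, tolerance = 1e-12)

  # bad channels are excluded from the reference but still shifted
  rec2 <- eeg_recording(matrix(c(1, 3, 100), 3, 1), srate = 1,
                        bad_channels = "ch3")
  car2 <- rereference_car(rec2)
  expect_equal(mean(car2$data[1:2, 1]), 0)

  allbad <- eeg_recording(matrix(0, 2, 3), srate = 1,
                          bad_channels = c("ch1", "ch2"))
  expect_error(rereference_car(allbad), class = "ps_no_reference")
})

test_that("quality gate applies the inclusion rules and the best-four ranking", {
  reps <- dplyr::bind_rows(lapply(1:5, function(s)
    quality_report(2, 200 + 10 * s, 200, session = s)))
  sel <- quality_gate(reps)
  # sessions ranked by total clean seconds: 5,4,3,2 survive
  expect_equal(sel$selected, 2:5)
  expect_false(sel$subject_excluded)

  # drop-first alternative when all five pass
  self <- quality_gate(reps, drop_first_if_all_pass = TRUE)
  expect_equal(self$selected, 2:5)

  # boundaries: 7 bad channels and exactly 180 s both fail
  expect_false(quality_report(7, 200, 200)$passed)
  expect_true(quality_report(6, 200, 200)$passed)
  expect_false(quality_report(2, 180, 200)$passed)

  # fewer than 4 passing sessions flags the subject
  bad <- dplyr::bind_rows(lapply(1:5, function(s)
    quality_report(ifelse(s <= 3, 9, 2), 200, 200, session = s)))
  gate <- quality_gate(bad)
  expect_equal(gate$selected, 4:5)
  expect_true(gate$subject_excluded)

  # pure function of its inputs
  expect_identical(quality_gate(reps)$selected, quality_gate(reps)$selected)
})
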