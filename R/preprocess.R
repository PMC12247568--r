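#' Resample a recording to a lower rate
#'
#' Rational-ratio resampling with an anti-alias FIR stage: the signal is
#' upsampled by zero-stuffing, low-pass filtered with a Hamming-windowed
#' sinc cut at the smaller of the two Nyquist frequencies (applied
#' zero-phase), and decimated. Only downsampling (or the identity) is
#' supported; the artifact mask is carried over by nearest-sample mapping.
#'
#' @param rec an [eeg_recording()].
#' @param target_rate new sampling rate in samples/s; must not exceed
#'   `rec$srate`.
#' @return The resampled `eeg_recording`.
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_rate > rec$srate) {
    stop_ps("upsampling not supported: target_rate exceeds recording rate",
            "ps_upsampling_not_supported")
  }
  if (target_rate == rec$srate) return(rec)

  # reduce target/srate to p/q in integers (rates may be non-integer)
  scale <- 1e6
  g0 <- gcd_int(round(target_rate * scale), round(rec$srate * scale))
  p <- round(target_rate * scale) / g0
  q <- round(rec$srate * scale) / g0
  if (p * ncol(rec$data) > 5e8) {
    stop_ps("resampling ratio too fine to realise", "ps_invalid_input")
  }

  n <- ncol(rec$data)
  half <- 10L * as.integer(max(p, q))
  # anti-alias cutoff at the output Nyquist, in cycles/sample of the
  # intermediate (upsampled) rate
  wc <- 1 / (2 * max(p, q))
  h <- hamming_sinc_lowpass(2L * half + 1L, wc)
  h <- h * p

  out <- t(apply(rec$data, 1L, function(x) {
    up <- numeric(n * p)
    up[seq(1L, by = p, length.out = n)] <- x
    filt <- Re(fft_convolve_same(up, h))
    idx <- seq(1L, length(up), by = q)
    filt[idx]
  }))

  n_out <- length(seq(1L, n * p, by = q))
  src <- pmin(n, pmax(1L, round((seq_len(n_out) - 1L) * q / p) + 1L))
  eeg_recording(out, srate = target_rate,
                channel_labels = rec$channel_labels,
                reference = rec$reference, bad_channels = rec$bad_channels,
                artifact_mask = rec$artifact_mask[src],
                interpolated = rec$interpolated)
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

# odd-length Hamming-windowed sinc low-pass; wc in cycles/sample (0..0.5)
hamming_sinc_lowpass <- function(n_taps, wc) {
  stopifnot(n_taps %% 2L == 1L)
  m <- (n_taps - 1L) / 2L
  t <- seq(-m, m)
  h <- 2 * wc * sinc_fun(2 * wc * t)
  w <- 0.54 + 0.46 * cos(pi * t / m)
  h <- h * w
  h / sum(h)
}

sinc_fun <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Band-pass filter with a Hamming-windowed sinc FIR
#'
#' High-pass followed by low-pass, both linear-phase Hamming-windowed sinc
#' kernels applied zero-phase (centred convolution), so the pass band keeps
#' its timing exactly. Transition widths default to the common rule
#' `min(max(0.25 * edge, 2 Hz), room-to-boundary)`; the -6 dB point of each
#' kernel sits at the stated band edge. The Hamming window yields roughly
#' 53 dB stop-band attenuation one transition width beyond each edge, and
#' the high-pass has an exact null at DC.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges in Hz, `0 < low < high < srate/2`.
#' @param trans_low,trans_high optional transition widths in Hz.
#' @return The filtered `eeg_recording`.
#' @export
bandpass_fir <- function(rec, low, high,
                         trans_low = NULL, trans_high = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$srate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop_ps("invalid band: need 0 < low < high < Nyquist", "ps_invalid_band")
  }
  trans_low <- trans_low %||% min(max(0.25 * low, 2), low)
  trans_high <- trans_high %||% min(max(0.25 * high, 2), nyq - high)

  h_lp_for_hp <- design_lowpass(rec$srate, low - trans_low / 2, trans_low)
  # spectral inversion: high-pass = delta - low-pass
  h_hp <- -h_lp_for_hp
  h_hp[(length(h_hp) + 1L) / 2L] <- h_hp[(length(h_hp) + 1L) / 2L] + 1
  h_lp <- design_lowpass(rec$srate, high + trans_high / 2, trans_high)

  out <- t(apply(rec$data, 1L, function(x) {
    y <- Re(fft_convolve_same(x, h_hp))
    Re(fft_convolve_same(y, h_lp))
  }))
  eeg_recording(out, srate = rec$srate, channel_labels = rec$channel_labels,
                reference = rec$reference, bad_channels = rec$bad_channels,
                artifact_mask = rec$artifact_mask,
                interpolated = rec$interpolated)
}

# Hamming-windowed sinc low-pass with -6 dB point at fc (Hz) and the given
# transition width (Hz); order from the Hamming design rule 3.3 / dF.
design_lowpass <- function(srate, fc, trans_hz) {
  n_taps <- ceiling(3.3 * srate / trans_hz)
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  hamming_sinc_lowpass(as.integer(n_taps), fc / srate)
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean over non-bad channels from every
#' channel, so the good-channel average is identically zero afterwards.
#'
#' @param rec an [eeg_recording()].
#' @return The re-referenced `eeg_recording` with `reference = "CAR"`.
#' @export
rereference_car <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  good <- good_channel_idx(rec)
  if (length(good) < 2) {
    stop_ps("common average needs at least 2 non-bad channels",
            "ps_no_reference")
  }
  avg <- colMeans(rec$data[good, , drop = FALSE])
  out <- sweep(rec$data, 2L, avg)
  eeg_recording(out, srate = rec$srate, channel_labels = rec$channel_labels,
                reference = "CAR", bad_channels = rec$bad_channels,
                artifact_mask = rec$artifact_mask,
                interpolated = rec$interpolated)
}
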