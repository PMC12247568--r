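#' Morlet wavelet bank specification
#'
#' Frequency grid and cycle counts for the time-frequency transform. The
#' grid runs from `f_low` to `f_high` inclusive in steps of `f_step`
#' (defaults: the alpha band, 8-12 Hz in 0.5 Hz steps). The number of
#' wavelet cycles interpolates linearly from `c_low` at the lower boundary
#' to `c_high` at the upper boundary, trading frequency resolution at the
#' top of the band for time resolution at the bottom.
#'
#' @param f_low,f_high band boundaries in Hz.
#' @param f_step grid step in Hz.
#' @param c_low,c_high cycles at the lower/upper boundary.
#' @return An object of class `wavelet_spec` with the resolved `freqs` grid.
#' @export
#' @examples
#' wavelet_spec()$freqs
wavelet_spec <- function(f_low = 8, f_high = 12, f_step = 0.5,
                         c_low = 4, c_high = 6) {
  stopifnot(f_low < f_high, f_step > 0, c_low <= c_high)
  freqs <- seq(f_low, f_high, by = f_step)
  structure(list(f_low = f_low, f_high = f_high, f_step = f_step,
                 c_low = c_low, c_high = c_high, freqs = freqs),
            class = "wavelet_spec")
}

#' Cycles per frequency bin
#'
#' Linear interpolation `c(f) = c_low + (c_high - c_low) * (f - f_low) /
#' (f_high - f_low)`, evaluated on the spec's frequency grid. A
#' single-frequency grid gets `c_low`.
#'
#' @param spec a [wavelet_spec()].
#' @param freqs frequencies to evaluate at (default: the spec's grid).
#' @return Numeric vector of cycle counts.
#' @export
wavelet_cycles <- function(spec, freqs = spec$freqs) {
  if (length(spec$freqs) == 1L || spec$f_high == spec$f_low) {
    return(rep(spec$c_low, length(freqs)))
  }
  spec$c_low + (spec$c_high - spec$c_low) *
    (freqs - spec$f_low) / (spec$f_high - spec$f_low)
}

# complex Morlet kernel at f Hz with n_cycles cycles; sigma_t =
# n_cycles / (2 pi f); support +-4 sigma_t; normalised so a unit-amplitude
# sinusoid at f returns modulus ~1
morlet_kernel <- function(f, n_cycles, srate) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(4 * sigma_t * srate)
  t <- seq(-half, half) / srate
  env <- exp(-t^2 / (2 * sigma_t^2))
  w <- env * exp(2i * pi * f * t)
  w / (sum(env) / 2)
}

#' Instantaneous phase and amplitude via Morlet wavelets
#'
#' Convolves each parcel time course with a bank of complex Morlet
#' wavelets and stores the argument (phase, wrapped to (-pi, pi]) and
#' modulus (amplitude) per parcel, frequency, and sample. Samples within
#' half the widest wavelet support of either recording edge — or of an
#' incoming invalid sample — are flagged invalid; downstream windows that
#' touch them are dropped.
#'
#' @param ts a [parcel_ts()].
#' @param spec a [wavelet_spec()].
#' @return An object of class `phase_tensor`: list with `phases` and
#'   `amplitudes` (parcels x frequencies x samples arrays), `freqs`,
#'   `srate`, `valid` (per-sample logical), `parcel_labels`.
#' @export
morlet_phase <- function(ts, spec = wavelet_spec()) {
  stopifnot(inherits(ts, "parcel_ts"), inherits(spec, "wavelet_spec"))
  n <- ncol(ts$data)
  p <- nrow(ts$data)
  freqs <- spec$freqs
  cycles <- wavelet_cycles(spec)
  kernels <- lapply(seq_along(freqs), function(i)
    morlet_kernel(freqs[i], cycles[i], ts$srate))
  max_half <- max(vapply(kernels, function(k) (length(k) - 1L) %/% 2L, 1L))
  if (n < 2L * max_half + 1L) {
    stop_ps("recording shorter than the widest wavelet support",
            "ps_too_short")
  }
  phases <- array(NA_real_, c(p, length(freqs), n))
  amplitudes <- array(NA_real_, c(p, length(freqs), n))
  for (fi in seq_along(freqs)) {
    w <- kernels[[fi]]
    for (pi_ in seq_len(p)) {
      cx <- fft_convolve_same(ts$data[pi_, ], w)
      phases[pi_, fi, ] <- Arg(cx)
      amplitudes[pi_, fi, ] <- Mod(cx)
    }
  }
  valid <- ts$valid
  valid[seq_len(max_half)] <- FALSE
  valid[(n - max_half + 1L):n] <- FALSE
  # dilate incoming artifact gaps by the half support
  if (any(!ts$valid)) {
    bad <- which(!ts$valid)
    lo <- pmax(1L, bad - max_half)
    hi <- pmin(n, bad + max_half)
    for (k in seq_along(bad)) valid[lo[k]:hi[k]] <- FALSE
  }
  structure(list(phases = phases, amplitudes = amplitudes, freqs = freqs,
                 srate = ts$srate, valid = valid,
                 parcel_labels = ts$parcel_labels),
            class = "phase_tensor")
}

#' @export
print.phase_tensor <- function(x, ...) {
  cat(sprintf(
    "<phase_tensor> %d parcels x %d freqs (%g-%g Hz) x %d samples @ %g Hz\n",
    dim(x$phases)[1], dim(x$phases)[2], min(x$freqs), max(x$freqs),
    dim(x$phases)[3], x$srate))
  cat(sprintf("  valid samples: %d / %d\n", sum(x$valid), length(x$valid)))
  invisible(x)
}
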