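#' Specification of a synthetic connectivity-state dataset
#'
#' Ground-truth generator for Markov-switching phase-locked subnetworks:
#' `k_states` recurring states, each realised by a subset of parcels
#' locked to a state-specific driver oscillation at `carrier_hz`. Within a
#' state's subnetwork, half the member parcels sit at phase offset 0 and
#' half at `lock_lag`, so every planted edge (a cross pair between the two
#' halves) carries a non-zero lag that ciPLV detects, while same-offset
#' pairs are zero-lag and are suppressed by construction. Non-member
#' parcels follow independent phase random walks around the carrier.
#' Signals are cosines of the phases plus 1/f background noise at
#' `background_snr` (signal/noise variance ratio).
#'
#' @param n_parcels number of parcels (default 20; use 150 for full-scale
#'   runs).
#' @param srate sampling rate, samples/s (default 128).
#' @param duration_s signal length in seconds (default 300).
#' @param k_states number of recurring states (default 4).
#' @param parcels_per_state subnetwork size per state (default 6, split
#'   3 + 3 across the two phase offsets).
#' @param carrier_hz oscillation frequency (default 10, mid-alpha).
#' @param lock_lag planted phase lag in radians (default `pi/2`, where
#'   ciPLV is maximal).
#' @param phase_noise_kappa von Mises concentration of the per-sample
#'   phase jitter of coupled parcels (default 20).
#' @param background_snr signal-to-noise variance ratio (default 3).
#' @param mean_dwell_ms mean state dwell time (default 600).
#' @param step_ms dwell-process resolution, matching the analysis hop
#'   (default 100).
#' @param coupling_tau_ms relaxation time constant of the phase pulling
#'   that locks a coupled parcel to its driver (default 10 ms). Phases
#'   evolve continuously: at a state switch a parcel slews to the new
#'   driver within a few tau rather than jumping.
#' @param release_tau_ms decay time constant of the coupling gain after a
#'   parcel's state ends (default 45 ms): an outgoing subnetwork
#'   desynchronises gradually, as coupled oscillators do, instead of
#'   unlocking instantaneously.
#' @param freq_spread_hz full width of the uniform spread of per-parcel
#'   intrinsic frequencies around the carrier (default 4, i.e. 8-12 Hz
#'   individual alpha frequencies). Detuning makes uncoupled pairs
#'   decohere within a window.
#' @param transition optional explicit k x k row-stochastic matrix
#'   overriding the dwell parameterisation.
#' @param state_edge_sets optional list (length `k_states`) of two-column
#'   matrices of parcel pairs; overrides the random subnetwork draw.
#'   Must then be accompanied by `state_offsets`, a list of per-parcel
#'   offset vectors (radians, `NA` = uncoupled).
#' @param state_offsets see `state_edge_sets`.
#' @param seed RNG seed; fully determines the dataset.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_parcels = 20, srate = 128, duration_s = 300,
                           k_states = 4, parcels_per_state = 6,
                           carrier_hz = 10, lock_lag = pi / 2,
                           phase_noise_kappa = 20, background_snr = 3,
                           mean_dwell_ms = 600, step_ms = 100,
                           coupling_tau_ms = 10, release_tau_ms = 45,
                           freq_spread_hz = 4,
                           transition = NULL, state_edge_sets = NULL,
                           state_offsets = NULL, seed = 1) {
  stopifnot(n_parcels >= 4, k_states >= 1,
            parcels_per_state <= n_parcels, srate > 0, duration_s > 0)
  if (!is.null(transition)) {
    stopifnot(nrow(transition) == k_states,
              all(abs(rowSums(transition) - 1) < 1e-9))
  }
  if (is.null(state_edge_sets)) {
    set.seed(seed)
    state_offsets <- vector("list", k_states)
    state_edge_sets <- vector("list", k_states)
    half <- floor(parcels_per_state / 2)
    for (s in seq_len(k_states)) {
      members <- sort(sample(n_parcels, parcels_per_state))
      grp_a <- members[seq_len(half)]
      grp_b <- members[(half + 1):parcels_per_state]
      off <- rep(NA_real_, n_parcels)
      off[grp_a] <- 0
      off[grp_b] <- lock_lag
      es <- expand.grid(a = grp_a, b = grp_b)
      es <- cbind(pmin(es$a, es$b), pmax(es$a, es$b))
      state_offsets[[s]] <- off
      state_edge_sets[[s]] <- es[order(es[, 1], es[, 2]), , drop = FALSE]
    }
  } else {
    stopifnot(length(state_edge_sets) == k_states,
              !is.null(state_offsets),
              length(state_offsets) == k_states)
    for (es in state_edge_sets) {
      if (any(es[, 1] == es[, 2]) || any(es > n_parcels) || any(es < 1)) {
        stop_ps("edge set contains self-pairs or out-of-range parcels",
                "ps_invalid_spec")
      }
    }
  }
  structure(list(
    n_parcels = n_parcels, srate = srate, duration_s = duration_s,
    k_states = k_states, parcels_per_state = parcels_per_state,
    carrier_hz = carrier_hz, lock_lag = lock_lag,
    phase_noise_kappa = phase_noise_kappa, background_snr = background_snr,
    mean_dwell_ms = mean_dwell_ms, step_ms = step_ms,
    coupling_tau_ms = coupling_tau_ms, release_tau_ms = release_tau_ms,
    freq_spread_hz = freq_spread_hz,
    transition = transition, state_edge_sets = state_edge_sets,
    state_offsets = state_offsets, seed = seed), class = "synthetic_spec")
}

#' Planted centroids of a synthetic spec
#'
#' @param spec a [synthetic_spec()].
#' @return k x n_pairs binary matrix, columns ordered as
#'   [make_pair_index()].
#' @export
planted_centroids <- function(spec) {
  pairs <- make_pair_index(spec$n_parcels)
  key <- paste(pairs$i, pairs$j)
  out <- matrix(0, spec$k_states, nrow(pairs))
  for (s in seq_len(spec$k_states)) {
    es <- spec$state_edge_sets[[s]]
    out[s, match(paste(es[, 1], es[, 2]), key)] <- 1
  }
  out
}

#' Simulate the per-sample state label sequence
#'
#' First-order Markov chain at the dwell-process resolution (`step_ms`),
#' expanded to samples. With the dwell parameterisation the
#' self-transition probability is `1 - step_ms / mean_dwell_ms`, giving
#' geometric dwell lengths with the requested mean; other transitions are
#' uniform.
#'
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed (defaults to the spec's).
#' @return List with `sample_labels` (length `duration_s * srate`),
#'   `step_labels`, and the `transition` matrix used.
#' @export
simulate_state_sequence <- function(spec, seed = spec$seed) {
  k <- spec$k_states
  n <- round(spec$duration_s * spec$srate)
  step_samples <- spec$step_ms * spec$srate / 1000
  n_steps <- ceiling(n / step_samples)
  if (k == 1L) {
    return(list(sample_labels = rep(1L, n), step_labels = rep(1L, n_steps),
                transition = matrix(1, 1, 1)))
  }
  tr <- spec$transition
  if (is.null(tr)) {
    stay <- max(0, 1 - spec$step_ms / spec$mean_dwell_ms)
    tr <- matrix((1 - stay) / (k - 1), k, k)
    diag(tr) <- stay
  }
  set.seed(seed + 1L)
  steps <- integer(n_steps)
  steps[1] <- sample.int(k, 1)
  for (t in 2:n_steps) {
    steps[t] <- sample.int(k, 1, prob = tr[steps[t - 1], ])
  }
  idx <- pmin(floor((seq_len(n) - 1) / step_samples) + 1L, n_steps)
  list(sample_labels = steps[idx], step_labels = steps, transition = tr)
}

# 1/f-shaped noise via spectral shaping of white Gaussian noise
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  sp <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # symmetric frequency index
  sp <- sp / sqrt(f)
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate phase-locked parcel signals
#'
#' Realises the spec: each state has its own driver phase (a random walk
#' around the carrier). Every parcel carries a continuous base phase that
#' advances at its intrinsic frequency (carrier plus an individual
#' detuning) with random-walk noise; while a parcel belongs to the active
#' state's subnetwork, its base phase is additionally pulled toward the
#' driver plus its planted offset with time constant `coupling_tau_ms`,
#' so phases never jump at state switches. The observed phase is the base
#' plus i.i.d. von Mises jitter (`phase_noise_kappa`) for coupled
#' parcels. Signals are cosines of the observed phases mixed with 1/f
#' background noise at the spec's SNR.
#'
#' @param spec a [synthetic_spec()].
#' @param labels optional per-sample labels (defaults to
#'   [simulate_state_sequence()]).
#' @param seed RNG seed (defaults to the spec's).
#' @return List with `ts` (a [parcel_ts()]), `ground_truth` (list:
#'   `sample_labels`, `planted_centroids`, `planted_coverage`,
#'   `transition`), and `phases` (the noiseless parcel phases).
#' @export
simulate_parcel_phases <- function(spec, labels = NULL, seed = spec$seed) {
  n <- round(spec$duration_s * spec$srate)
  p <- spec$n_parcels
  if (is.null(labels)) {
    sim <- simulate_state_sequence(spec, seed = seed)
    labels <- sim$sample_labels
    tr <- sim$transition
  } else {
    if (length(labels) != n) {
      stop_ps("labels length must equal duration * srate", "ps_invalid_spec")
    }
    tr <- spec$transition
  }
  set.seed(seed + 2L)
  omega <- 2 * pi * spec$carrier_hz / spec$srate
  # per-state drivers: carrier plus a slow random walk
  drivers <- matrix(0, spec$k_states, n)
  for (s in seq_len(spec$k_states)) {
    dw <- cumsum(c(stats::runif(1, -pi, pi),
                   stats::rnorm(n - 1, sd = 0.05)))
    drivers[s, ] <- dw + omega * seq_len(n)
  }
  # per-parcel intrinsic frequencies (individual alpha) and offsets table
  detune <- 2 * pi * stats::runif(p, -spec$freq_spread_hz / 2,
                                  spec$freq_spread_hz / 2) / spec$srate
  offsets <- do.call(rbind, spec$state_offsets)   # k x p, NA = uncoupled
  gain <- 1000 / (spec$coupling_tau_ms * spec$srate)  # per-sample pull
  release <- exp(-1000 / (spec$release_tau_ms * spec$srate))
  bg_sd <- 0.3
  walk <- matrix(stats::rnorm(p * n, sd = bg_sd), p, n)
  base <- matrix(0, p, n)
  base[, 1] <- stats::runif(p, -pi, pi)
  # per-parcel coupling state: gain decays after the parcel's state ends,
  # still tracking the last driver/offset, so subnetworks unlock smoothly
  cur_gain <- rep(0, p)
  cur_state <- rep(1L, p)
  cur_off <- rep(0, p)
  for (t in 2:n) {
    s <- labels[t]
    off_now <- offsets[s, ]
    coupled <- !is.na(off_now)
    cur_gain[coupled] <- gain
    cur_state[coupled] <- s
    cur_off[coupled] <- off_now[coupled]
    cur_gain[!coupled] <- cur_gain[!coupled] * release
    tgt <- drivers[cbind(cur_state, t)] + cur_off
    pull <- cur_gain * sin(tgt - base[, t - 1])
    base[, t] <- base[, t - 1] + omega + detune + pull + walk[, t]
  }
  # observed phase: base plus i.i.d. von Mises jitter on coupled samples
  phases <- base
  for (s in seq_len(spec$k_states)) {
    active <- which(labels == s)
    if (!length(active)) next
    off <- spec$state_offsets[[s]]
    for (j in which(!is.na(off))) {
      phases[j, active] <- phases[j, active] +
        rvonmises(length(active), spec$phase_noise_kappa)
    }
  }
  phases <- wrap_phase(phases)
  signal <- cos(phases)
  noise_sd <- sqrt(0.5 / spec$background_snr)
  noise <- t(vapply(seq_len(p), function(i) pink_noise(n) * noise_sd,
                    numeric(n)))
  ts <- parcel_ts(signal + noise, srate = spec$srate)
  cent <- planted_centroids(spec)
  cover <- 100 * tabulate(labels, spec$k_states) / n
  list(ts = ts,
       ground_truth = list(sample_labels = labels,
                           planted_centroids = cent,
                           planted_coverage = cover,
                           transition = tr),
       phases = phases)
}

#' Majority window labels from per-sample ground truth
#'
#' Derives the planted label of each analysis window as the majority
#' per-sample label inside it (ties to the lower state index).
#'
#' @param sample_labels per-sample planted labels.
#' @param window_starts 0-based window start samples (as stored on a
#'   [sliding_ciplv()] result).
#' @param t_win samples per window.
#' @param k number of states.
#' @return Integer window labels.
#' @export
window_truth_labels <- function(sample_labels, window_starts, t_win,
                                k = max(sample_labels)) {
  vapply(window_starts, function(s) {
    counts <- tabulate(sample_labels[(s + 1):(s + t_win)], k)
    which.max(counts)
  }, integer(1))
}

#' Simulate a sensor recording of alternating topographies
#'
#' Microstate fixture: `k` random orthonormal zero-mean topographies; each
#' sample is the active topography scaled by a GFP envelope, with a random
#' polarity flip per sample, plus Gaussian channel noise. The common
#' average is zero by construction.
#'
#' @param k number of topographies.
#' @param channels channel count (`k <= channels`).
#' @param labels per-sample active topography (integers 1..k).
#' @param noise_sd channel noise standard deviation relative to the
#'   unit-norm maps.
#' @param seed RNG seed.
#' @param srate sampling rate attached to the output (default 128).
#' @return List with `rec` (an [eeg_recording()], CAR-referenced) and
#'   `maps` (k x channels planted topographies).
#' @export
simulate_sensor_maps <- function(k, channels, labels, noise_sd = 0.3,
                                 seed = 1, srate = 128) {
  stopifnot(k <= channels, all(labels %in% seq_len(k)))
  set.seed(seed)
  g <- matrix(stats::rnorm(channels * k), channels, k)
  g <- sweep(g, 2L, colMeans(g))       # zero-mean columns: CAR-compatible
  q <- qr.Q(qr(g))[, seq_len(k), drop = FALSE]
  n <- length(labels)
  env <- 1 + 0.5 * abs(sin(2 * pi * seq_len(n) / srate))
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  x <- q[, labels, drop = FALSE] *
    matrix(rep(env * sgn, each = channels), channels, n)
  x <- x + matrix(stats::rnorm(channels * n, sd = noise_sd), channels, n)
  rec <- rereference_car(eeg_recording(x, srate = srate))
  list(rec = rec, maps = t(q))
}
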