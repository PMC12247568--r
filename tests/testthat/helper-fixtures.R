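# shared fixtures, all generated in code

wrap_phase_for_test <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

# window-level planted data: binary edge vectors drawn from k disjoint-ish
# random centroids, with a fraction of edges swapped on<->off per window
make_window_data <- function(k = 4, n_parcels = 20, n_windows = 400,
                             noise = 0.1, seed = 1) {
  set.seed(seed)
  npair <- choose(n_parcels, 2)
  n_keep <- floor(0.1 * npair)
  cents <- t(sapply(seq_len(k), function(s) {
    v <- rep(0, npair)
    v[sample(npair, n_keep)] <- 1
    v
  }))
  labels <- sample(seq_len(k), n_windows, replace = TRUE)
  x <- cents[labels, , drop = FALSE]
  nfl <- round(noise * n_keep)
  if (nfl > 0) {
    for (i in seq_len(n_windows)) {
      on <- which(x[i, ] == 1)
      off <- which(x[i, ] == 0)
      x[i, sample(on, nfl)] <- 0
      x[i, sample(off, nfl)] <- 1
    }
  }
  list(x = x, labels = labels, centroids = cents,
       n_keep = n_keep, k = k)
}

# accuracy after optimal label matching of fitted centroids to planted ones
matched_accuracy <- function(fit_labels, true_labels, fit_centroids,
                             true_centroids) {
  perm <- align_labels(list(centroids = fit_centroids),
                       list(centroids = true_centroids))
  mean(perm[fit_labels] == true_labels)
}

# small multi-sinusoid recording
sine_recording <- function(freqs, srate = 128, secs = 10, channels = 2) {
  t <- seq_len(srate * secs) / srate
  x <- rowSums(sapply(freqs, function(f) sin(2 * pi * f * t)))
  eeg_recording(matrix(rep(x, each = channels), channels), srate = srate)
}

# write a BrainVision fixture (header + data) into dir; returns vhdr path
write_brainvision_fixture <- function(dir, data, srate,
                                      format = c("ascii", "float32",
                                                 "int16"),
                                      orientation = "MULTIPLEXED",
                                      resolution = 1) {
  format <- match.arg(format)
  vhdr <- file.path(dir, "rec.vhdr")
  dat <- file.path(dir, "rec.eeg")
  n_chan <- nrow(data)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "DataFile=rec.eeg",
    sprintf("NumberOfChannels=%d", n_chan),
    sprintf("SamplingInterval=%.10g", 1e6 / srate),
    sprintf("DataFormat=%s", if (format == "ascii") "ASCII" else "BINARY"),
    sprintf("DataOrientation=%s", orientation))
  if (format != "ascii") {
    hdr <- c(hdr, "[Binary Infos]",
             sprintf("BinaryFormat=%s",
                     if (format == "float32") "IEEE_FLOAT_32" else "INT_16"))
  }
  hdr <- c(hdr, "[Channel Infos]",
           sprintf("Ch%d=C%d,,%.10g,µV", seq_len(n_chan),
                   seq_len(n_chan), resolution))
  writeLines(hdr, vhdr)
  vals <- if (orientation == "MULTIPLEXED") as.vector(data) else
    as.vector(t(data))
  if (format == "ascii") {
    m <- if (orientation == "MULTIPLEXED") t(data) else data
    writeLines(apply(m, 1, paste, collapse = " "), dat)
  } else if (format == "float32") {
    writeBin(as.numeric(vals), dat, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(vals)), dat, size = 2, endian = "little")
  }
  vhdr
}

# exact two-sided signed-rank p by full 2^n enumeration (untied data)
enum_signed_rank_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- drop(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- if (v_obs > mu) 2 * mean(vs >= v_obs) else 2 * mean(vs <= v_obs)
  min(1, p)
}

# ICC(3,1) consistency via explicit sums of squares
icc_ss_oracle <- function(m) {
  n <- nrow(m); d <- ncol(m)
  gm <- mean(m); rm_ <- rowMeans(m); cm_ <- colMeans(m)
  ssr <- d * sum((rm_ - gm)^2)
  sse <- sum((m - outer(rm_, rep(1, d)) - outer(rep(1, n), cm_) + gm)^2)
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (d - 1))
  (msr - mse) / (msr + (d - 1) * mse)
}

# remap pair columns under a parcel permutation: column for (i,j) moves to
# the column of (perm[i], perm[j])
pair_permutation <- function(n_parcels, perm) {
  pairs <- make_pair_index(n_parcels)
  key <- paste(pmin(perm[pairs$i], perm[pairs$j]),
               pmax(perm[pairs$i], perm[pairs$j]))
  match(key, paste(pairs$i, pairs$j))
}
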