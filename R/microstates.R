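#' Global field power
#'
#' Per-sample population standard deviation of the scalp potential across
#' channels — the classical GFP of a CAR-referenced recording.
#'
#' @param rec an [eeg_recording()] (or channels x samples matrix).
#' @return Numeric vector, one value per sample.
#' @export
#' @examples
#' gfp(eeg_recording(matrix(c(1, -1), 2, 1), srate = 1))  # 1
gfp <- function(rec) {
  x <- if (inherits(rec, "eeg_recording")) rec$data else as.matrix(rec)
  mu <- colMeans(x)
  sqrt(colMeans(x^2) - mu^2)
}

# polarity-invariant assignment: index of map maximising (map . x)^2
ms_assign <- function(x, maps) {
  a <- maps %*% x          # k x samples activations
  max.col(t(a^2), ties.method = "first")
}

# dominant spatial direction (unit norm) of a channels x n sample block
dominant_map <- function(xk) {
  if (ncol(xk) == 1L) return(xk[, 1] / sqrt(sum(xk[, 1]^2)))
  v <- svd(xk, nu = 1, nv = 0)$u[, 1]
  v / sqrt(sum(v^2))
}

ms_gev <- function(x, maps, labels) {
  a <- maps[labels, , drop = FALSE]
  expl <- rowSums(t(x) * a)          # map_{L(t)} . x_t
  sum(expl^2) / sum(x^2)
}

#' Fit sensor-level microstates (polarity-invariant modified k-means)
#'
#' Clusters the per-sample scalp topographies of a CAR-referenced
#' recording into `k` unit-norm maps. Assignment uses maximal squared
#' spatial correlation (so a map and its negation are the same state) and
#' each map update is the dominant spatial direction (first left singular
#' vector) of its assigned samples. The best of `n_init` seeded restarts
#' by global explained variance (GEV) is returned. All samples enter the
#' segmentation (no GFP-peak subsampling, no temporal smoothing) unless
#' `gfp_peaks_only = TRUE`.
#'
#' @param rec an [eeg_recording()].
#' @param k number of microstates (default 4).
#' @param n_init restarts (default 10).
#' @param seed RNG seed.
#' @param gfp_peaks_only fit on local GFP maxima only.
#' @param max_iter iteration cap per restart.
#' @return An object of class `microstate_model`: `maps` (k x channels,
#'   unit rows, sign arbitrary), `gev`, `k`, `seed`, `n_init`,
#'   `channel_labels`.
#' @export
fit_microstates <- function(rec, k = 4, n_init = 10, seed = 1,
                            gfp_peaks_only = FALSE, max_iter = 100L) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$data[, rec$artifact_mask, drop = FALSE]
  if (gfp_peaks_only) {
    g <- gfp(x)
    pk <- which(diff(sign(diff(g))) < 0) + 1L
    if (length(pk) >= k) x <- x[, pk, drop = FALSE]
  }
  n <- ncol(x)
  if (n < k) stop_ps("fewer samples than microstates", "ps_insufficient_data")
  set.seed(seed)
  best <- NULL
  for (init in seq_len(n_init)) {
    idx <- sample(n, k)
    maps <- t(x[, idx, drop = FALSE])
    maps <- maps / sqrt(rowSums(maps^2))
    labels <- ms_assign(x, maps)
    for (it in seq_len(max_iter)) {
      for (j in seq_len(k)) {
        sel <- labels == j
        if (!any(sel)) {
          # re-seed an empty state at the worst-explained sample
          a <- maps[labels, , drop = FALSE]
          resid <- colSums(x^2) - rowSums(t(x) * a)^2
          maps[j, ] <- x[, which.max(resid)] /
            sqrt(sum(x[, which.max(resid)]^2))
        } else {
          maps[j, ] <- dominant_map(x[, sel, drop = FALSE])
        }
      }
      new_labels <- ms_assign(x, maps)
      if (identical(new_labels, labels)) break
      labels <- new_labels
    }
    gev <- ms_gev(x, maps, labels)
    if (is.null(best) || gev > best$gev) {
      best <- list(maps = maps, gev = gev)
    }
  }
  structure(list(maps = unname(best$maps), gev = best$gev, k = as.integer(k),
                 seed = seed, n_init = n_init,
                 channel_labels = rec$channel_labels),
            class = "microstate_model")
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> k=%d, %d channels, GEV %.3f\n",
              x$k, ncol(x$maps), x$gev))
  invisible(x)
}

#' Group-level microstate maps from subject models
#'
#' Pools the subject maps (k rows per subject) and re-clusters them with
#' the same polarity-invariant modified k-means, treating each subject map
#' as one observation.
#'
#' @param models list of [fit_microstates()] models over identical
#'   channels.
#' @param k group states (defaults to the subject k).
#' @param n_init,seed as in [fit_microstates()].
#' @return A `microstate_model` fitted to the pooled maps.
#' @export
fit_microstates_group <- function(models, k = NULL, n_init = 10, seed = 1) {
  dims <- vapply(models, function(m) ncol(m$maps), 1L)
  if (length(unique(dims)) != 1L) {
    stop_ps("models have incompatible channel dimensions",
            "ps_incompatible_models")
  }
  k <- k %||% models[[1]]$k
  pooled <- do.call(rbind, lapply(models, function(m) m$maps))
  rec <- eeg_recording(t(pooled), srate = 1,
                       channel_labels = models[[1]]$channel_labels)
  out <- fit_microstates(rec, k = k, n_init = n_init, seed = seed)
  out
}

#' Backfit microstate labels to a recording
#'
#' Labels every sample with the map of maximal squared spatial
#' correlation (polarity-invariant). Coverage and transition metrics apply
#' to the resulting label sequence via [state_coverage()] and
#' [transition_matrix()].
#'
#' @param rec an [eeg_recording()] with channels matching the model.
#' @param model a [fit_microstates()] model.
#' @return An object of class `microstate_seq`: `labels` (per clean
#'   sample), `gfp`, `k`, `srate`.
#' @export
backfit_microstates <- function(rec, model) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(model, "microstate_model"))
  if (nrow(rec$data) != ncol(model$maps)) {
    stop_ps("channel mismatch between recording and model",
            "ps_incompatible_models")
  }
  x <- rec$data[, rec$artifact_mask, drop = FALSE]
  structure(list(labels = ms_assign(x, model$maps), gfp = gfp(x),
                 k = model$k, srate = rec$srate),
            class = "microstate_seq")
}

#' @export
print.microstate_seq <- function(x, ...) {
  cat(sprintf("<microstate_seq> %d samples, k=%d\n", length(x$labels), x$k))
  invisible(x)
}
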