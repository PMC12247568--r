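#' Sliding-window specification
#'
#' Window geometry for the time-resolved connectivity measure: window
#' length and hop in milliseconds (defaults 300 / 100 ms — 200 ms overlap,
#' 100 ms time resolution). The per-window sample count is
#' `T = floor(window_ms * srate / 1000)` and window `k` (0-based) starts at
#' sample `round(k * step_ms * srate / 1000)`, so runs are bit-reproducible
#' at non-integer samples-per-hop.
#'
#' @param window_ms window length, ms.
#' @param step_ms hop between window starts, ms; `0 < step_ms <= window_ms`.
#' @return An object of class `sliding_window_spec`.
#' @export
sliding_window_spec <- function(window_ms = 300, step_ms = 100) {
  stopifnot(step_ms > 0, step_ms <= window_ms)
  structure(list(window_ms = window_ms, step_ms = step_ms),
            class = "sliding_window_spec")
}

window_samples <- function(spec, srate) {
  t_win <- floor(spec$window_ms * srate / 1000)
  if (t_win < 2) stop_ps("window shorter than 2 samples", "ps_window_too_short")
  as.integer(t_win)
}

#' Corrected imaginary phase-locking value of one window
#'
#' For a phase-difference series \eqn{\Delta\phi(t)}, let
#' \eqn{S = \frac{1}{T}\sum_t \exp(i\,\Delta\phi(t))}. The ciPLV is
#' \eqn{|\mathrm{Im}(S)| / \sqrt{1 - \mathrm{Re}(S)^2}}: the imaginary part
#' of the mean phasor, renormalised to discount the real (zero-lag) part.
#' It is 1 exactly for perfect locking at a \eqn{\pm\pi/2} lag and 0 for
#' zero-lag locking, which volume conduction / source leakage produces
#' artificially. The degenerate case \eqn{|\mathrm{Re}(S)| = 1} (perfect
#' zero-lag lock) is defined as 0, consistent with that suppression.
#'
#' @param delta_phase numeric vector of phase differences (radians),
#'   length `T >= 2`.
#' @param signed if `TRUE`, return the signed value
#'   `Im(S)/sqrt(1 - Re(S)^2)` (sign carries lag direction); the default
#'   magnitude lies in `[0, 1]`.
#' @return A single ciPLV value.
#' @export
#' @examples
#' ciplv_window(rep(pi / 2, 38)) # 1
#' ciplv_window(rep(0, 38))      # 0
ciplv_window <- function(delta_phase, signed = FALSE) {
  if (length(delta_phase) < 2) {
    stop_ps("window too short: need T >= 2 phase differences",
            "ps_window_too_short")
  }
  if (!all(is.finite(delta_phase))) {
    stop_ps("non-finite phase difference", "ps_invalid_input")
  }
  re <- mean(cos(delta_phase))
  im <- mean(sin(delta_phase))
  denom2 <- 1 - re^2
  if (denom2 <= 1e-12) return(0)
  val <- im / sqrt(denom2)
  if (signed) val else min(abs(val), 1)
}

#' Sliding-window ciPLV over all parcel pairs
#'
#' Computes the ciPLV for every unordered parcel pair in every sliding
#' window, per frequency bin, and aggregates across the frequency grid
#' (default: arithmetic mean of the per-bin magnitudes; `aggregate =
#' "pooled"` instead pools the phase differences of all bins into one
#' window). Windows overlapping invalid samples are dropped;
#' `window_starts` records the surviving 0-based start samples.
#'
#' @param pt a [phase_tensor()].
#' @param spec a [sliding_window_spec()].
#' @param aggregate `"mean"` (per-bin ciPLV averaged over bins) or
#'   `"pooled"` (phase differences pooled across bins before the ciPLV).
#' @param chunk_pairs pairs processed per block (memory control at large P).
#' @return An object of class `conn_series`: `values` (windows x pairs,
#'   in `[0, 1]`), `pair_index` (see [make_pair_index()]), `window_starts`
#'   (0-based samples), `t_win`, `srate`, `parcel_labels`.
#' @export
sliding_ciplv <- function(pt, spec = sliding_window_spec(),
                          aggregate = c("mean", "pooled"),
                          chunk_pairs = 2000L) {
  stopifnot(inherits(pt, "phase_tensor"))
  aggregate <- match.arg(aggregate)
  p <- dim(pt$phases)[1]
  nf <- dim(pt$phases)[2]
  n <- dim(pt$phases)[3]
  t_win <- window_samples(spec, pt$srate)
  step <- spec$step_ms * pt$srate / 1000

  starts <- integer(0)
  k <- 0L
  repeat {
    s <- round(k * step)
    if (s + t_win > n) break
    starts <- c(starts, as.integer(s))
    k <- k + 1L
  }
  if (!length(starts)) stop_ps("no window fits the data", "ps_empty_series")

  # a window is kept iff all its samples are valid
  cbad <- cumsum(!pt$valid)
  nbad <- cbad[starts + t_win] - c(0, cbad)[starts + 1L]
  keep <- nbad == 0L
  starts <- starts[keep]
  if (!length(starts)) stop_ps("no artifact-free window", "ps_empty_series")
  nw <- length(starts)

  pairs <- make_pair_index(p, pt$parcel_labels)
  npair <- nrow(pairs)
  values <- matrix(0, nw, npair)

  # rows x samples matrix -> rows x nw matrix of window means
  win_means <- function(m) {
    cm <- matrix(0, nrow(m), ncol(m) + 1L)
    for (r in seq_len(nrow(m))) cm[r, -1L] <- cumsum(m[r, ])
    (cm[, starts + t_win + 1L, drop = FALSE] -
       cm[, starts + 1L, drop = FALSE]) / t_win
  }
  ciplv_of <- function(re_w, im_w) {
    denom2 <- pmax(1 - re_w^2, 0)
    ifelse(denom2 <= 1e-12, 0, pmin(abs(im_w) / sqrt(denom2), 1))
  }

  for (block in split(seq_len(npair),
                      ceiling(seq_len(npair) / chunk_pairs))) {
    i1 <- pairs$i[block]
    i2 <- pairs$j[block]
    acc <- matrix(0, length(block), nw)   # per-bin ciPLV sum ("mean" mode)
    re_sum <- matrix(0, length(block), nw)
    im_sum <- matrix(0, length(block), nw)
    for (fi in seq_len(nf)) {
      ph <- matrix(pt$phases[, fi, ], nrow = p)
      co <- cos(ph); si <- sin(ph)
      re_t <- co[i1, , drop = FALSE] * co[i2, , drop = FALSE] +
        si[i1, , drop = FALSE] * si[i2, , drop = FALSE]
      im_t <- si[i1, , drop = FALSE] * co[i2, , drop = FALSE] -
        co[i1, , drop = FALSE] * si[i2, , drop = FALSE]
      re_w <- win_means(re_t)
      im_w <- win_means(im_t)
      if (aggregate == "mean") {
        acc <- acc + ciplv_of(re_w, im_w)
      } else {
        re_sum <- re_sum + re_w
        im_sum <- im_sum + im_w
      }
    }
    values[, block] <- if (aggregate == "mean") {
      t(acc / nf)
    } else {
      t(ciplv_of(re_sum / nf, im_sum / nf))
    }
  }

  structure(list(values = values, pair_index = pairs,
                 window_starts = starts, t_win = t_win,
                 step_ms = spec$step_ms, srate = pt$srate,
                 parcel_labels = pt$parcel_labels),
            class = "conn_series")
}

#' @export
print.conn_series <- function(x, ...) {
  cat(sprintf("<conn_series> %d windows x %d pairs (T=%d samples, hop %g ms)\n",
              nrow(x$values), ncol(x$values), x$t_win, x$step_ms))
  invisible(x)
}

#' Binary dynamic graph from proportional thresholding
#'
#' Per window, keeps exactly `n_keep = floor(fraction * n_pairs)` edges
#' with the largest connectivity values — the sparse "top fraction"
#' representation that emphasises the most robust connections. Ties at the
#' cut are broken deterministically toward the lower pair index.
#'
#' @param cs a [sliding_ciplv()] result.
#' @param fraction proportion of pairs retained per window (default 0.10).
#' @return An object of class `dynamic_graph`: `edges` (windows x pairs
#'   logical matrix, each row summing to `n_keep`), `n_keep`, plus the
#'   window/pair metadata of `cs`.
#' @export
threshold_top_fraction <- function(cs, fraction = 0.10) {
  stopifnot(inherits(cs, "conn_series"))
  if (!(fraction > 0 && fraction <= 1)) {
    stop_ps("fraction must be in (0, 1]", "ps_invalid_input")
  }
  npair <- ncol(cs$values)
  n_keep <- floor(fraction * npair)
  if (n_keep < 1) {
    stop_ps("degenerate threshold: floor(fraction * n_pairs) == 0",
            "ps_degenerate_threshold")
  }
  edges <- matrix(FALSE, nrow(cs$values), npair)
  for (w in seq_len(nrow(cs$values))) {
    ord <- order(-cs$values[w, ], seq_len(npair))
    edges[w, ord[seq_len(n_keep)]] <- TRUE
  }
  structure(list(edges = edges, n_keep = as.integer(n_keep),
                 pair_index = cs$pair_index, window_starts = cs$window_starts,
                 t_win = cs$t_win, step_ms = cs$step_ms, srate = cs$srate,
                 parcel_labels = cs$parcel_labels),
            class = "dynamic_graph")
}

#' @export
print.dynamic_graph <- function(x, ...) {
  cat(sprintf("<dynamic_graph> %d windows, %d vertices, %d edges/window\n",
              nrow(x$edges), length(x$parcel_labels), x$n_keep))
  invisible(x)
}

#' Per-window edge list of a dynamic graph
#'
#' @param g a [threshold_top_fraction()] result.
#' @return Tibble with columns `window`, `window_start`, `parcel_a`,
#'   `parcel_b`.
#' @export
edge_list <- function(g) {
  stopifnot(inherits(g, "dynamic_graph"))
  idx <- which(g$edges, arr.ind = TRUE)
  tibble::tibble(
    window = idx[, 1],
    window_start = g$window_starts[idx[, 1]],
    parcel_a = g$parcel_labels[g$pair_index$i[idx[, 2]]],
    parcel_b = g$parcel_labels[g$pair_index$j[idx[, 2]]]
  ) |> dplyr::arrange(.data$window)
}
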