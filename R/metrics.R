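#' State coverage
#'
#' Percentage of windows spent in each state; sums to 100 across states.
#'
#' @param seq an [assign_states()] result, or an integer label vector.
#' @param k number of states (taken from `seq` when available).
#' @return Tibble with columns `state` (1..k) and `coverage` (percent).
#' @export
#' @examples
#' state_coverage(c(1, 1, 2, 4, 4, 4, 4, 4, 4, 4), k = 4)
state_coverage <- function(seq, k = NULL) {
  labels <- if (inherits(seq, "state_seq")) seq$labels else as.integer(seq)
  k <- k %||% if (inherits(seq, "state_seq")) seq$k else max(labels)
  if (length(labels) < 1) stop_ps("need at least one window", "ps_invalid_input")
  counts <- tabulate(labels, nbins = k)
  tibble::tibble(state = seq_len(k), coverage = 100 * counts / length(labels))
}

# contiguous segment id per window, from window starts and the hop
segment_ids <- function(seq) {
  n <- length(seq$labels)
  starts <- seq$window_starts
  if (is.null(starts) || is.null(seq$step_ms) || is.null(seq$srate)) {
    return(rep(1L, n))
  }
  step <- seq$step_ms * seq$srate / 1000
  breaks <- c(FALSE, diff(starts) > 1.5 * step)
  cumsum(breaks) + 1L
}

#' Empirical first-order transition matrix
#'
#' Transition probabilities between consecutive windows, counted only
#' within contiguous segments (windows separated by an artifact gap never
#' contribute a transition). With `include_self = FALSE` the diagonal is
#' removed before row normalisation, giving the conditional distribution
#' of the next *different* state. Rows of states that never transition are
#' `NA` (undefined), not zero.
#'
#' @param seq an [assign_states()] result or integer label vector.
#' @param k number of states.
#' @param include_self keep self-transitions (default `TRUE`).
#' @return A k x k row-stochastic matrix (rows may be `NA`).
#' @export
transition_matrix <- function(seq, k = NULL, include_self = TRUE) {
  labels <- if (inherits(seq, "state_seq")) seq$labels else as.integer(seq)
  k <- k %||% if (inherits(seq, "state_seq")) seq$k else max(labels)
  if (length(labels) < 2) stop_ps("need at least two windows", "ps_invalid_input")
  segs <- if (inherits(seq, "state_seq")) segment_ids(seq)
          else rep(1L, length(labels))
  counts <- matrix(0, k, k)
  from <- labels[-length(labels)]
  to <- labels[-1L]
  same_seg <- segs[-length(segs)] == segs[-1L]
  for (idx in which(same_seg)) counts[from[idx], to[idx]] <-
      counts[from[idx], to[idx]] + 1
  if (!include_self) diag(counts) <- 0
  rs <- rowSums(counts)
  out <- counts / rs
  out[rs == 0, ] <- NA_real_
  dimnames(out) <- list(from = seq_len(k), to = seq_len(k))
  out
}

#' Mean dwell time per state
#'
#' Mean length of consecutive same-state runs (within contiguous
#' segments), in windows and in milliseconds (`runs x step_ms`).
#'
#' @param seq an [assign_states()] result or integer label vector.
#' @param k number of states.
#' @param step_ms hop duration used to convert runs to time (taken from
#'   `seq` when available).
#' @return Tibble with `state`, `n_runs`, `mean_dwell_windows`,
#'   `mean_dwell_ms`.
#' @export
mean_dwell <- function(seq, k = NULL, step_ms = NULL) {
  labels <- if (inherits(seq, "state_seq")) seq$labels else as.integer(seq)
  k <- k %||% if (inherits(seq, "state_seq")) seq$k else max(labels)
  step_ms <- step_ms %||% if (inherits(seq, "state_seq")) seq$step_ms
  segs <- if (inherits(seq, "state_seq")) segment_ids(seq)
          else rep(1L, length(labels))
  runs <- data.frame(state = integer(), len = integer())
  for (s in split(labels, segs)) {
    r <- rle(s)
    runs <- rbind(runs, data.frame(state = r$values, len = r$lengths))
  }
  out <- tibble::tibble(state = seq_len(k))
  agg <- lapply(seq_len(k), function(st) {
    l <- runs$len[runs$state == st]
    c(n = length(l), m = if (length(l)) mean(l) else NA_real_)
  })
  out$n_runs <- vapply(agg, `[[`, numeric(1), "n")
  out$mean_dwell_windows <- vapply(agg, `[[`, numeric(1), "m")
  out$mean_dwell_ms <- out$mean_dwell_windows *
    (if (is.null(step_ms)) NA_real_ else step_ms)
  out
}

#' Summarise a state sequence
#'
#' Bundles coverage, the transition matrix (both with and without
#' self-transitions), and mean dwell times into one object.
#'
#' @param seq an [assign_states()] result.
#' @return An object of class `state_metrics`.
#' @export
state_metrics <- function(seq) {
  stopifnot(inherits(seq, "state_seq"))
  structure(list(
    coverage = state_coverage(seq),
    transitions = transition_matrix(seq, include_self = TRUE),
    transitions_noself = transition_matrix(seq, include_self = FALSE),
    dwell = mean_dwell(seq),
    k = seq$k, subject = seq$subject, session = seq$session,
    task = seq$task), class = "state_metrics")
}

#' @export
print.state_metrics <- function(x, ...) {
  cat(sprintf("<state_metrics> k=%d\n", x$k))
  print(x$coverage)
  invisible(x)
}
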