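# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ps <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "phasestates_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Unordered parcel-pair index
#'
#' Enumerates all unordered pairs (m < n) of `n_items` vertices in the fixed
#' order used throughout the package: (1,2), (1,3), ..., (1,P), (2,3), ...
#' Every windows-by-pairs matrix (ciPLV values, binary edges, state
#' centroids) is column-indexed by this enumeration.
#'
#' @param n_items number of vertices (parcels).
#' @param labels optional vertex labels attached to the output.
#' @return A tibble with columns `pair` (index), `i`, `j` (1-based vertex
#'   indices, `i < j`) and, when labels are given, `label_i`, `label_j`.
#' @export
#' @examples
#' make_pair_index(4)
make_pair_index <- function(n_items, labels = NULL) {
  if (n_items < 2) stop_ps("need at least 2 vertices", "ps_invalid_input")
  i <- rep.int(seq_len(n_items - 1L), times = (n_items - 1L):1L)
  j <- unlist(lapply(seq_len(n_items - 1L), function(a) (a + 1L):n_items),
              use.names = FALSE)
  out <- tibble::tibble(pair = seq_along(i), i = i, j = j)
  if (!is.null(labels)) {
    stopifnot(length(labels) == n_items)
    out$label_i <- labels[i]
    out$label_j <- labels[j]
  }
  out
}

n_pairs_of <- function(p) as.integer(p * (p - 1L) / 2L)

# FFT linear convolution, 'same' alignment: returns length(x) samples
# centred on the kernel midpoint ((nw+1)/2 for odd nw).
fft_convolve_same <- function(x, w) {
  nx <- length(x)
  nw <- length(w)
  n <- nx + nw - 1L
  X <- stats::fft(c(x, rep(0, n - nx)))
  W <- stats::fft(c(w, rep(0, n - nw)))
  full <- stats::fft(X * W, inverse = TRUE) / n
  half <- (nw - 1L) %/% 2L
  full[(half + 1L):(half + nx)]
}

# wrap radians into (-pi, pi]
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

# draw von Mises(0, kappa) deviates (Best & Fisher rejection sampler);
# kappa = 0 falls back to uniform
rvonmises <- function(n, kappa) {
  if (kappa <= 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    nok <- sum(ok)
    if (nok > 0) {
      out[(got + 1L):(got + nok)] <- sign(u3[ok] - 0.5) * acos(f[ok])
      got <- got + nok
    }
  }
  out
}

# all permutations of 1..k (k small)
all_perms <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_perms(k - 1L)
  out <- vector("list", k * length(sub))
  idx <- 1L
  for (s in sub) {
    for (pos in 0:(k - 1L)) {
      out[[idx]] <- as.integer(append(s, k, after = pos))
      idx <- idx + 1L
    }
  }
  out
}
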