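#' Parcel time-series container
#'
#' Source-space activity collapsed to one time course per atlas parcel
#' (rows) — the input to the wavelet/connectivity stages.
#'
#' @param data numeric matrix, parcels x samples.
#' @param srate sampling rate in samples/s.
#' @param parcel_labels one label per row (atlas region names when known).
#' @param valid optional logical per-sample clean mask.
#' @return An object of class `parcel_ts`.
#' @export
parcel_ts <- function(data, srate, parcel_labels = NULL, valid = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(parcel_labels)) {
    parcel_labels <- rownames(data) %||% paste0("parcel", seq_len(nrow(data)))
  }
  if (nrow(data) != length(parcel_labels)) {
    stop_ps("parcel label count must equal row count", "ps_invalid_input")
  }
  if (is.null(valid)) valid <- rep(TRUE, ncol(data))
  stopifnot(length(valid) == ncol(data), srate > 0)
  rownames(data) <- parcel_labels
  structure(list(data = data, srate = as.numeric(srate),
                 parcel_labels = parcel_labels, valid = as.logical(valid)),
            class = "parcel_ts")
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> %d parcels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate))
  invisible(x)
}

#' @export
dim.parcel_ts <- function(x) dim(x$data)

#' Dominant orientation of a set of source normals
#'
#' First principal direction (leading right singular vector) of a
#' vertices-by-3 matrix of unit normal vectors, with its sign fixed so that
#' the majority of normals point into the same half-space (non-negative dot
#' product).
#'
#' @param normals numeric matrix, vertices x 3, rows of unit norm.
#' @return A unit 3-vector.
#' @export
dominant_orientation <- function(normals) {
  normals <- as.matrix(normals)
  if (nrow(normals) < 1 || ncol(normals) != 3) {
    stop_ps("normals must be a vertices x 3 matrix", "ps_invalid_input")
  }
  nrm <- sqrt(rowSums(normals^2))
  if (any(nrm < 1e-12)) {
    stop_ps("zero-norm normal vector", "ps_invalid_orientation")
  }
  v <- svd(normals, nu = 0, nv = 1)$v[, 1]
  dots <- drop(normals %*% v)
  if (sum(dots < 0) > sum(dots > 0)) {
    v <- -v
  } else if (sum(dots < 0) == sum(dots > 0)) {
    # balanced cloud: canonical sign, largest-magnitude component positive
    if (v[which.max(abs(v))] < 0) v <- -v
  }
  v / sqrt(sum(v^2))
}

#' Collapse vertex source estimates into parcel time courses
#'
#' For each parcel, finds the dominant orientation of its vertices'
#' normals, negates the time course of every vertex whose normal opposes
#' it (negative dot product — the standard sign-flip that prevents
#' cancellation of anti-aligned dipoles), and averages the (possibly
#' flipped) vertex time courses.
#'
#' @param data numeric matrix, vertices x samples.
#' @param normals numeric matrix, vertices x 3 unit orientation vectors.
#' @param parcel_map integer vector mapping each vertex to a parcel id in
#'   `1..P` (or `0..P-1`; a zero-based map is shifted up).
#' @param srate sampling rate in samples/s.
#' @param parcel_labels optional labels, length `P`.
#' @return A [parcel_ts()] with one row per parcel.
#' @export
sign_flip_parcel_average <- function(data, normals, parcel_map, srate,
                                     parcel_labels = NULL) {
  data <- as.matrix(data)
  normals <- as.matrix(normals)
  stopifnot(nrow(data) == nrow(normals), nrow(data) == length(parcel_map))
  parcel_map <- as.integer(parcel_map)
  if (min(parcel_map) == 0L) parcel_map <- parcel_map + 1L
  n_parcels <- max(parcel_map)
  present <- sort(unique(parcel_map))
  missing <- setdiff(seq_len(n_parcels), present)
  if (length(missing)) {
    stop_ps(sprintf("empty parcel(s): %s",
                    paste(missing, collapse = ", ")), "ps_empty_parcel")
  }
  out <- matrix(0, n_parcels, ncol(data))
  for (p in present) {
    idx <- which(parcel_map == p)
    dom <- dominant_orientation(normals[idx, , drop = FALSE])
    flip <- ifelse(drop(normals[idx, , drop = FALSE] %*% dom) < 0, -1, 1)
    out[p, ] <- colMeans(data[idx, , drop = FALSE] * flip)
  }
  if (is.null(parcel_labels)) parcel_labels <- paste0("parcel", seq_len(n_parcels))
  parcel_ts(out, srate = srate, parcel_labels = parcel_labels)
}
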