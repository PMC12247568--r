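# Seeded best-of-n restarts around stats::kmeans. Initial centers are k
# distinct data rows sampled per restart (never duplicated, so the engine
# cannot reject them); the fit with the lowest total within-cluster sum of
# squares wins. Deterministic given `seed`.
best_kmeans <- function(x, k, n_init, seed) {
  if (nrow(x) < k) {
    stop_ps("fewer observations than clusters", "ps_insufficient_data")
  }
  dup <- duplicated(x)
  distinct_rows <- which(!dup)
  if (length(distinct_rows) < k) {
    stop_ps("fewer distinct observations than clusters",
            "ps_insufficient_data")
  }
  if (length(distinct_rows) == k) {
    # exactly k distinct patterns: the optimum is the patterns themselves
    centers <- x[distinct_rows, , drop = FALSE]
    d2 <- dist_to_centroids(x, centers)
    cl <- max.col(-d2, ties.method = "first")
    return(list(centers = centers, cluster = cl,
                tot.withinss = sum(d2[cbind(seq_len(nrow(x)), cl)])))
  }
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    fit <- NULL
    for (attempt in 1:5) {
      init <- x[sample(distinct_rows, k), , drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = init, iter.max = 100L)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop_ps("k-means failed on all restarts", "ps_kmeans_failed")
  best
}

as_window_matrix <- function(g) {
  if (inherits(g, "dynamic_graph")) {
    m <- g$edges * 1
  } else {
    m <- as.matrix(g) * 1
  }
  storage.mode(m) <- "double"
  m
}

#' Fit connectivity states to one subject's dynamic graph
#'
#' k-means (Euclidean) on the per-window binary edge vectors: each window
#' is a point in pair space, each resulting centroid is a vector of mean
#' edge occupancies in `[0, 1]` — a recurring connectivity pattern. The
#' best of `n_init` seeded restarts (lowest within-cluster sum of squares)
#' is kept.
#'
#' @param g a [threshold_top_fraction()] result, or a windows x pairs
#'   0/1 matrix.
#' @param k number of states.
#' @param n_init restarts (default 10).
#' @param seed RNG seed; fixes the fit completely.
#' @return An object of class `state_model`: `centroids` (k x pairs),
#'   `inertia`, `labels` (training assignment), `k`, `level`, `seed`,
#'   `n_init`, `pair_index`.
#' @export
fit_states <- function(g, k, n_init = 10, seed = 1) {
  x <- as_window_matrix(g)
  fit <- best_kmeans(x, k, n_init, seed)
  structure(list(centroids = unname(fit$centers), k = as.integer(k),
                 inertia = fit$tot.withinss, labels = unname(fit$cluster),
                 level = "subject", seed = seed, n_init = n_init,
                 pair_index = if (inherits(g, "dynamic_graph")) g$pair_index),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> %s level, k=%d, %d pairs, inertia %.3f\n",
              x$level, x$k, ncol(x$centroids), x$inertia))
  invisible(x)
}

#' Group-level connectivity states from subject models
#'
#' Second-level k-means over the pooled subject centroids (each subject
#' model contributes its k centroid rows), with the same seeded
#' best-of-restarts rule; the group centroids are mean edge occupancies
#' over the subject centroids in each cluster.
#'
#' @param models list of subject [fit_states()] models with a common pair
#'   dimension.
#' @param k number of group states (defaults to the subject models' k).
#' @param n_init,seed as in [fit_states()].
#' @return A `state_model` with `level = "group"`.
#' @export
fit_states_group <- function(models, k = NULL, n_init = 10, seed = 1) {
  dims <- vapply(models, function(m) ncol(m$centroids), 1L)
  if (length(unique(dims)) != 1L) {
    stop_ps("subject models have incompatible pair dimensions",
            "ps_incompatible_models")
  }
  k <- k %||% models[[1]]$k
  pooled <- do.call(rbind, lapply(models, function(m) m$centroids))
  fit <- best_kmeans(pooled, k, n_init, seed)
  structure(list(centroids = unname(fit$centers), k = as.integer(k),
                 inertia = fit$tot.withinss, labels = unname(fit$cluster),
                 level = "group", seed = seed, n_init = n_init,
                 pair_index = models[[1]]$pair_index),
            class = "state_model")
}

#' Assign windows to the nearest state
#'
#' Labels each window of a dynamic graph with the Euclidean-nearest
#' centroid of a fitted model; ties go to the lowest state index.
#'
#' @param g a [threshold_top_fraction()] result or windows x pairs matrix.
#' @param model a [fit_states()] / [fit_states_group()] model with
#'   matching pair dimension.
#' @param subject,session,task optional identifiers carried into the
#'   result.
#' @return An object of class `state_seq`: `labels` (1-based state per
#'   window), `k`, `window_starts`, `step_ms`, `srate`, identifiers.
#' @export
assign_states <- function(g, model, subject = NA, session = NA, task = NA) {
  x <- as_window_matrix(g)
  if (ncol(x) != ncol(model$centroids)) {
    stop_ps("pair dimension mismatch between graph and model",
            "ps_incompatible_models")
  }
  d2 <- dist_to_centroids(x, model$centroids)
  labels <- max.col(-d2, ties.method = "first")
  structure(list(labels = labels, k = model$k,
                 window_starts = if (inherits(g, "dynamic_graph")) g$window_starts,
                 step_ms = if (inherits(g, "dynamic_graph")) g$step_ms,
                 srate = if (inherits(g, "dynamic_graph")) g$srate,
                 subject = subject, session = session, task = task),
            class = "state_seq")
}

# squared Euclidean distances, rows of x vs rows of centroids
dist_to_centroids <- function(x, centroids) {
  xc <- x %*% t(centroids)
  sweep(-2 * xc, 2L, rowSums(centroids^2), `+`) + rowSums(x^2)
}

#' @export
print.state_seq <- function(x, ...) {
  cat(sprintf("<state_seq> %d windows, k=%d\n", length(x$labels), x$k))
  invisible(x)
}

#' Inertia-vs-k curve and elbow selection
#'
#' Fits states for each candidate `k` (best of `n_init` restarts each) and
#' selects the elbow of the inertia curve. The default `"curvature"` rule
#' takes the `k` with the largest discrete second difference of inertia —
#' the point where adding one more cluster stops paying; it localises the
#' bend better than the `"chord"` rule (maximum perpendicular distance to
#' the chord joining the curve's endpoints, after scaling both axes to
#' `[0, 1]`), which drifts with the grid endpoints on long flat tails. A
#' flat curve (no inertia range) returns the smallest `k` with a warning.
#'
#' @param g a [threshold_top_fraction()] result or windows x pairs matrix.
#' @param k_grid ascending candidate values (default 2:10).
#' @param n_init,seed as in [fit_states()]; seeds per k derive
#'   deterministically from `seed`.
#' @param rule `"curvature"` (default) or `"chord"`.
#' @return An object of class `elbow_curve`: tibble-like list with
#'   `k_grid`, `inertia`, `k_star`.
#' @export
elbow_select_k <- function(g, k_grid = 2:10, n_init = 10, seed = 1,
                           rule = c("curvature", "chord")) {
  rule <- match.arg(rule)
  x <- as_window_matrix(g)
  stopifnot(!is.unsorted(k_grid), max(k_grid) < nrow(x))
  inertia <- vapply(seq_along(k_grid), function(i) {
    fit_states(x, k_grid[i], n_init = n_init, seed = seed + i)$inertia
  }, numeric(1))
  rng <- diff(range(inertia))
  if (rng <= max(1e-12, 1e-9 * max(abs(inertia), 1))) {
    warning("flat inertia curve; returning smallest k")
    k_star <- k_grid[1]
  } else if (rule == "curvature" && length(k_grid) >= 3) {
    drop_ <- -diff(inertia)
    curv <- drop_[-length(drop_)] - drop_[-1]
    k_star <- k_grid[which.max(curv) + 1L]
  } else {
    kk <- (k_grid - k_grid[1]) / (k_grid[length(k_grid)] - k_grid[1])
    ii <- (inertia - inertia[length(inertia)]) / rng
    # distance from (kk, ii) to the chord between the endpoints
    p1 <- c(kk[1], ii[1]); p2 <- c(kk[length(kk)], ii[length(ii)])
    v <- p2 - p1
    d <- abs(v[2] * (kk - p1[1]) - v[1] * (ii - p1[2])) / sqrt(sum(v^2))
    k_star <- k_grid[which.max(d)]
  }
  structure(list(k_grid = as.integer(k_grid), inertia = inertia,
                 k_star = as.integer(k_star)),
            class = "elbow_curve")
}

#' @export
print.elbow_curve <- function(x, ...) {
  cat(sprintf("<elbow_curve> k in [%d, %d], selected k* = %d\n",
              min(x$k_grid), max(x$k_grid), x$k_star))
  invisible(x)
}

#' Optimal label alignment between two state models
#'
#' Permutation of the model's states minimising the total Euclidean
#' distance to the reference centroids (exhaustive optimal assignment for
#' `k <= 8`, greedy beyond). `perm[i] = j` means model state `i` matches
#' reference state `j`; relabel a sequence with `perm[labels]`.
#'
#' @param model,reference `state_model`s (or plain centroid matrices) with
#'   equal `k` and pair dimension.
#' @param polarity_invariant match centroid rows up to sign (used for
#'   microstate maps).
#' @return Integer permutation vector of length `k`.
#' @export
align_labels <- function(model, reference, polarity_invariant = FALSE) {
  cm <- if (is.matrix(model)) model else model$centroids
  cr <- if (is.matrix(reference)) reference else reference$centroids
  if (!all(dim(cm) == dim(cr))) {
    stop_ps("models must share k and pair dimension", "ps_incompatible_models")
  }
  k <- nrow(cm)
  cost <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    d <- sum((cm[i, ] - cr[j, ])^2)
    if (polarity_invariant) d <- min(d, sum((cm[i, ] + cr[j, ])^2))
    cost[i, j] <- d
  }
  if (k <= 8L) {
    perms <- all_perms(k)
    tot <- vapply(perms, function(p) sum(cost[cbind(seq_len(k), p)]),
                  numeric(1))
    perms[[which.min(tot)]]
  } else {
    perm <- integer(k)
    free <- seq_len(k)
    for (i in order(apply(cost, 1L, min))) {
      j <- free[which.min(cost[i, free])]
      perm[i] <- j
      free <- setdiff(free, j)
    }
    perm
  }
}

#' Canonical state order of a group model
#'
#' A deterministic display convention: states ordered by descending
#' concentration (sum of their largest 100 centroid occupancies), which
#' places focal, strongly-occupied patterns first and the diffuse
#' all-to-all low-occupancy pattern last.
#'
#' @param model a `state_model`.
#' @return Integer order such that `model$centroids[order, ]` is canonical.
#' @export
canonical_state_order <- function(model) {
  conc <- apply(model$centroids, 1L, function(r) {
    sum(sort(r, decreasing = TRUE)[seq_len(min(100L, length(r)))])
  })
  order(-conc, seq_len(model$k))
}
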