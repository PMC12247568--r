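#' Tidy a fitted state model
#'
#' One row per state x parcel pair, with the centroid's mean edge
#' occupancy.
#'
#' @param x a [fit_states()] / [fit_states_group()] model.
#' @param ... unused.
#' @return Tibble with `state`, `pair`, `i`, `j`, `occupancy`.
#' @export
#' @method tidy state_model
tidy.state_model <- function(x, ...) {
  np <- ncol(x$centroids)
  pairs <- x$pair_index %||% make_pair_index(
    (1 + sqrt(1 + 8 * np)) / 2)
  tibble::tibble(
    state = rep(seq_len(x$k), each = np),
    pair = rep(pairs$pair, x$k),
    i = rep(pairs$i, x$k),
    j = rep(pairs$j, x$k),
    occupancy = as.vector(t(x$centroids)))
}

#' @rdname tidy.state_model
#' @export
#' @method glance state_model
glance.state_model <- function(x, ...) {
  tibble::tibble(k = x$k, level = x$level, inertia = x$inertia,
                 n_pairs = ncol(x$centroids), seed = x$seed,
                 n_init = x$n_init)
}

#' Tidy microstate maps
#'
#' @param x a [fit_microstates()] model.
#' @param ... unused.
#' @return Tibble with `state`, `channel`, `weight`.
#' @export
#' @method tidy microstate_model
tidy.microstate_model <- function(x, ...) {
  tibble::tibble(
    state = rep(seq_len(x$k), each = ncol(x$maps)),
    channel = rep(x$channel_labels, x$k),
    weight = as.vector(t(x$maps)))
}

#' @rdname tidy.microstate_model
#' @export
#' @method glance microstate_model
glance.microstate_model <- function(x, ...) {
  tibble::tibble(k = x$k, gev = x$gev, n_channels = ncol(x$maps),
                 seed = x$seed, n_init = x$n_init)
}

#' Tidy an elbow curve
#'
#' @param x an [elbow_select_k()] result.
#' @param ... unused.
#' @return Tibble with `k`, `inertia`, `selected`.
#' @export
#' @method tidy elbow_curve
tidy.elbow_curve <- function(x, ...) {
  tibble::tibble(k = x$k_grid, inertia = x$inertia,
                 selected = x$k_grid == x$k_star)
}

#' @rdname tidy.elbow_curve
#' @export
#' @method glance elbow_curve
glance.elbow_curve <- function(x, ...) {
  tibble::tibble(k_star = x$k_star, k_min = min(x$k_grid),
                 k_max = max(x$k_grid))
}

#' Tidy state metrics
#'
#' @param x a [state_metrics()] result.
#' @param ... unused.
#' @return Coverage and dwell joined, one row per state.
#' @export
#' @method tidy state_metrics
tidy.state_metrics <- function(x, ...) {
  dplyr::left_join(x$coverage, x$dwell, by = "state")
}

#' Plot an inertia-vs-k curve with the selected elbow
#'
#' @param object an [elbow_select_k()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @method autoplot elbow_curve
autoplot.elbow_curve <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$inertia)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "number of states k",
                  y = "within-cluster sum of squares",
                  title = sprintf("Elbow selection: k* = %d", object$k_star))
}

#' Plot state coverages
#'
#' @param object a [state_metrics()] result.
#' @param ... unused.
#' @return A ggplot bar chart of per-state coverage.
#' @export
#' @method autoplot state_metrics
autoplot.state_metrics <- function(object, ...) {
  df <- object$coverage
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$state),
                                   y = .data$coverage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "state", y = "coverage (%)")
}

#' Plot state centroids as an edge-occupancy heat map
#'
#' @param object a `state_model`.
#' @param ... unused.
#' @return A ggplot tile plot, pairs on x, states on y.
#' @export
#' @method autoplot state_model
autoplot.state_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = factor(.data$state),
                                   fill = .data$occupancy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "parcel pair", y = "state", fill = "occupancy")
}

#' Plot microstate topographies as channel-by-state weights
#'
#' @param object a `microstate_model`.
#' @param ... unused.
#' @return A ggplot tile plot (sign is arbitrary per map).
#' @export
#' @method autoplot microstate_model
autoplot.microstate_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel,
                                   y = factor(.data$state),
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "channel", y = "microstate", fill = "weight") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
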