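#' Run the connectivity-state pipeline over a cohort
#'
#' For every manifest row (one subject-session-task recording of parcel
#' time courses): wavelet phases, sliding-window ciPLV, proportional
#' thresholding, and a subject-level state fit. Subject centroids are then
#' pooled into a group model — by default jointly over the tasks so state
#' labels correspond across RS1/RS2 (set `group_mode = "per_task"` to
#' cluster tasks separately) — every window sequence is backfitted to the
#' group centroids, and coverage, transition, and reliability statistics
#' are assembled as tidy tables. A failing row is isolated with its error
#' recorded; the cohort run continues.
#'
#' @param manifest tibble with columns `subject`, `session`, `task`, and
#'   either a list-column `ts` of [parcel_ts()] objects or a `path` column
#'   of [read_parcel_tsv()] files.
#' @param wavelet a [wavelet_spec()].
#' @param window a [sliding_window_spec()].
#' @param fraction proportional threshold (default 0.10).
#' @param k number of states (default 4).
#' @param n_init k-means restarts (default 10).
#' @param seed base RNG seed; per-row seeds derive deterministically.
#' @param group_mode `"joint"` or `"per_task"`.
#' @return A list: `subject_models`, `group_models` (one per mode/task),
#'   `coverage` (tidy tibble), `metrics` (per-row [state_metrics()]),
#'   `comparisons` (Wilcoxon table via [compare_coverages()]), `icc`
#'   (via [reliability_icc()]), `errors`, `params`.
#' @export
run_connectivity_pipeline <- function(manifest, wavelet = wavelet_spec(),
                                      window = sliding_window_spec(),
                                      fraction = 0.10, k = 4, n_init = 10,
                                      seed = 7,
                                      group_mode = c("joint", "per_task")) {
  group_mode <- match.arg(group_mode)
  stopifnot(all(c("subject", "session", "task") %in% names(manifest)))
  n <- nrow(manifest)
  graphs <- vector("list", n)
  models <- vector("list", n)
  errors <- list()
  for (r in seq_len(n)) {
    res <- tryCatch({
      ts <- if ("ts" %in% names(manifest)) manifest$ts[[r]]
            else read_parcel_tsv(manifest$path[r])
      pt <- morlet_phase(ts, wavelet)
      cs <- sliding_ciplv(pt, window)
      g <- threshold_top_fraction(cs, fraction)
      list(g = g, m = fit_states(g, k, n_init = n_init, seed = seed + r))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- tibble::tibble(
        row = r, subject = manifest$subject[r],
        session = manifest$session[r], task = manifest$task[r],
        message = conditionMessage(res))
    } else {
      graphs[[r]] <- res$g
      models[[r]] <- res$m
    }
  }
  ok <- which(!vapply(models, is.null, logical(1)))
  if (!length(ok)) stop_ps("every cohort row failed", "ps_pipeline_failed")

  group_models <- list()
  if (group_mode == "joint") {
    gm <- fit_states_group(models[ok], k = k, n_init = n_init, seed = seed)
    ord <- canonical_state_order(gm)
    gm$centroids <- gm$centroids[ord, , drop = FALSE]
    group_models[["all"]] <- gm
  } else {
    for (tk in unique(manifest$task[ok])) {
      sel <- ok[manifest$task[ok] == tk]
      gm <- fit_states_group(models[sel], k = k, n_init = n_init,
                             seed = seed)
      ord <- canonical_state_order(gm)
      gm$centroids <- gm$centroids[ord, , drop = FALSE]
      group_models[[tk]] <- gm
    }
  }

  metrics <- vector("list", n)
  cov_rows <- list()
  for (r in ok) {
    gm <- if (group_mode == "joint") group_models[["all"]]
          else group_models[[manifest$task[r]]]
    seq_r <- assign_states(graphs[[r]], gm,
                           subject = manifest$subject[r],
                           session = manifest$session[r],
                           task = manifest$task[r])
    metrics[[r]] <- state_metrics(seq_r)
    cv <- metrics[[r]]$coverage
    cv$subject <- manifest$subject[r]
    cv$session <- manifest$session[r]
    cv$task <- manifest$task[r]
    cov_rows[[length(cov_rows) + 1L]] <- cv
  }
  coverage <- dplyr::bind_rows(cov_rows)

  comparisons <- tryCatch(compare_coverages(coverage, test = "wilcoxon"),
                          error = function(e) NULL)
  icc <- tryCatch(reliability_icc(coverage), error = function(e) NULL)

  list(subject_models = models, group_models = group_models,
       coverage = coverage, metrics = metrics, comparisons = comparisons,
       icc = icc,
       errors = if (length(errors)) dplyr::bind_rows(errors)
                else tibble::tibble(),
       params = list(wavelet = wavelet, window = window,
                     fraction = fraction, k = k, n_init = n_init,
                     seed = seed, group_mode = group_mode))
}

#' Run the sensor-level microstate pipeline over a cohort
#'
#' Per manifest row: polarity-invariant microstate fit of the recording;
#' then a pooled group model, per-row backfitting, coverage tables, paired
#' t comparisons, and across-day ICC.
#'
#' @param manifest tibble with `subject`, `session`, `task`, and a
#'   list-column `rec` of [eeg_recording()]s (or a `path` column of
#'   BrainVision headers).
#' @param k microstates (default 4).
#' @param n_init,seed as in [fit_microstates()].
#' @return A list mirroring [run_connectivity_pipeline()] with
#'   `group_model` a [fit_microstates_group()] fit and `comparisons` a
#'   paired-t table.
#' @export
run_microstate_pipeline <- function(manifest, k = 4, n_init = 10, seed = 7) {
  stopifnot(all(c("subject", "session", "task") %in% names(manifest)))
  n <- nrow(manifest)
  recs <- vector("list", n)
  models <- vector("list", n)
  errors <- list()
  for (r in seq_len(n)) {
    res <- tryCatch({
      rec <- if ("rec" %in% names(manifest)) manifest$rec[[r]]
             else read_brainvision(manifest$path[r])
      list(rec = rec,
           m = fit_microstates(rec, k = k, n_init = n_init, seed = seed + r))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- tibble::tibble(
        row = r, subject = manifest$subject[r],
        session = manifest$session[r], task = manifest$task[r],
        message = conditionMessage(res))
    } else {
      recs[[r]] <- res$rec
      models[[r]] <- res$m
    }
  }
  ok <- which(!vapply(models, is.null, logical(1)))
  if (!length(ok)) stop_ps("every cohort row failed", "ps_pipeline_failed")

  group_model <- fit_microstates_group(models[ok], k = k, n_init = n_init,
                                       seed = seed)
  cov_rows <- list()
  for (r in ok) {
    seq_r <- backfit_microstates(recs[[r]], group_model)
    cv <- state_coverage(seq_r$labels, k = k)
    cv$subject <- manifest$subject[r]
    cv$session <- manifest$session[r]
    cv$task <- manifest$task[r]
    cov_rows[[length(cov_rows) + 1L]] <- cv
  }
  coverage <- dplyr::bind_rows(cov_rows)
  comparisons <- tryCatch(compare_coverages(coverage, test = "t"),
                          error = function(e) NULL)
  icc <- tryCatch(reliability_icc(coverage), error = function(e) NULL)

  list(subject_models = models, group_model = group_model,
       coverage = coverage, comparisons = comparisons, icc = icc,
       errors = if (length(errors)) dplyr::bind_rows(errors)
                else tibble::tibble(),
       params = list(k = k, n_init = n_init, seed = seed))
}
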