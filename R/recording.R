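#' Sensor EEG recording container
#'
#' A light matrix-backed container for multichannel scalp EEG: a
#' channels-by-samples voltage matrix (microvolts) plus sampling rate,
#' channel labels, the current reference, a set of bad channels, and a
#' per-sample artifact mask (`TRUE` = clean).
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param srate sampling rate in samples/s, > 0.
#' @param channel_labels character vector, one label per row of `data`.
#' @param reference reference description; `"CAR"` after common-average
#'   re-referencing.
#' @param bad_channels character vector, subset of `channel_labels`.
#' @param artifact_mask logical vector, one entry per sample; `TRUE` marks
#'   clean samples. Defaults to all clean.
#' @param interpolated character vector of channels whose signal was
#'   reconstructed upstream (flagged, never recomputed here).
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(4 * 256), 4), srate = 128,
#'                      channel_labels = c("Fz", "Cz", "Pz", "Oz"))
#' rec
eeg_recording <- function(data, srate, channel_labels = NULL,
                          reference = "unknown", bad_channels = character(),
                          artifact_mask = NULL, interpolated = character()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channel_labels)) {
    channel_labels <- rownames(data) %||% paste0("ch", seq_len(nrow(data)))
  }
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0) {
    stop_ps("srate must be a single positive number", "ps_invalid_input")
  }
  if (nrow(data) != length(channel_labels)) {
    stop_ps("row count of data must equal number of channel labels",
            "ps_invalid_input")
  }
  if (is.null(artifact_mask)) artifact_mask <- rep(TRUE, ncol(data))
  if (length(artifact_mask) != ncol(data)) {
    stop_ps("artifact_mask length must equal sample count", "ps_invalid_input")
  }
  if (!all(bad_channels %in% channel_labels)) {
    stop_ps("bad_channels must be a subset of channel_labels",
            "ps_invalid_input")
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, srate = as.numeric(srate),
         channel_labels = channel_labels, reference = reference,
         bad_channels = bad_channels,
         artifact_mask = as.logical(artifact_mask),
         interpolated = interpolated),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), ref=%s\n",
    nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate, x$reference))
  if (length(x$bad_channels)) {
    cat("  bad channels:", paste(x$bad_channels, collapse = ", "), "\n")
  }
  n_bad <- sum(!x$artifact_mask)
  if (n_bad) cat(sprintf("  artifact samples: %d (%.1f s)\n",
                         n_bad, n_bad / x$srate))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

good_channel_idx <- function(rec) {
  which(!(rec$channel_labels %in% rec$bad_channels))
}

#' Per-session quality report
#'
#' Summarises a session against the dataset-inclusion rules: fewer than 7
#' excluded channels and more than 180 s of artifact-free data in each of
#' the two resting-state runs. `clean_seconds_*` count cumulative clean
#' time, not the longest contiguous stretch.
#'
#' @param n_bad_channels number of excluded channels.
#' @param clean_seconds_rs1,clean_seconds_rs2 cumulative artifact-free
#'   seconds in the pre-task (RS1) and post-task (RS2) resting runs.
#' @param session optional session identifier carried through to
#'   [quality_gate()].
#' @return A one-row tibble of class `quality_report` with a `passed` flag.
#' @export
quality_report <- function(n_bad_channels, clean_seconds_rs1,
                           clean_seconds_rs2, session = NA_integer_) {
  out <- tibble::tibble(
    session = session,
    n_bad_channels = as.integer(n_bad_channels),
    clean_seconds_rs1 = as.numeric(clean_seconds_rs1),
    clean_seconds_rs2 = as.numeric(clean_seconds_rs2),
    passed = n_bad_channels < 7 & clean_seconds_rs1 > 180 &
      clean_seconds_rs2 > 180
  )
  class(out) <- c("quality_report", class(out))
  out
}

#' Select sessions passing the quality gate
#'
#' Keeps sessions that pass the inclusion rules and, when more than
#' `max_sessions` pass, retains the `max_sessions` sessions with the most
#' total clean data (RS1 + RS2 seconds), ties broken by earlier session
#' index. Alternatively, `drop_first_if_all_pass = TRUE` drops the first
#' passing session when all sessions pass, mirroring the habituation-based
#' convention of excluding day one. A subject is flagged excluded when
#' fewer than 4 of 5 sessions pass (or fewer than `min_pass` generally).
#'
#' @param reports a tibble of [quality_report()] rows (stackable with
#'   `dplyr::bind_rows()`).
#' @param max_sessions number of sessions to retain (default 4).
#' @param min_pass minimum passing sessions for subject inclusion
#'   (default 4).
#' @param drop_first_if_all_pass if `TRUE` and every session passes, drop
#'   the earliest session instead of ranking by clean seconds.
#' @return A list with `selected` (integer row indices into `reports`, in
#'   session order), `subject_excluded` (logical), and `reports` with a
#'   `selected` column added.
#' @export
#' @examples
#' reps <- dplyr::bind_rows(lapply(1:5, function(s)
#'   quality_report(2, 200 + s, 200, session = s)))
#' quality_gate(reps)$selected
quality_gate <- function(reports, max_sessions = 4, min_pass = 4,
                         drop_first_if_all_pass = FALSE) {
  if (nrow(reports) < 1) stop_ps("need at least one report", "ps_invalid_input")
  pass <- which(reports$passed)
  total_clean <- reports$clean_seconds_rs1 + reports$clean_seconds_rs2
  if (length(pass) > max_sessions) {
    if (drop_first_if_all_pass && length(pass) == nrow(reports)) {
      keep <- pass[-1L]
      keep <- keep[seq_len(min(max_sessions, length(keep)))]
    } else {
      ord <- pass[order(-total_clean[pass], pass)]
      keep <- sort(ord[seq_len(max_sessions)])
    }
  } else {
    keep <- pass
  }
  reports$selected <- seq_len(nrow(reports)) %in% keep
  list(selected = keep,
       subject_excluded = length(pass) < min_pass,
       reports = reports)
}
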