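#' Read a BrainVision recording
#'
#' Parses the `.vhdr` header (INI syntax) and loads the companion data
#' file. Supported layouts: binary `INT_16`, `INT_32`, `IEEE_FLOAT_32`
#' and ASCII numbers, in multiplexed (sample-major) or vectorized
#' (channel-major) orientation. Channel resolutions from the header are
#' applied so values come out in microvolts. Markers are not interpreted;
#' the artifact mask starts all-clean.
#'
#' @param vhdr path to the `.vhdr` header file.
#' @return An [eeg_recording()].
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, warn = FALSE)
  section <- ""
  kv <- list()
  channels <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- tolower(gsub("\\[|\\]", "", ln))
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) next
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    if (section == "channel infos") {
      channels[[key]] <- val
    } else {
      kv[[paste(section, tolower(key))]] <- val
    }
  }
  need <- function(k) {
    v <- kv[[k]]
    if (is.null(v)) stop_ps(paste("missing header field:", k),
                            "ps_bad_header")
    v
  }
  n_chan <- as.integer(need("common infos numberofchannels"))
  srate <- 1e6 / as.numeric(need("common infos samplinginterval"))
  fmt <- toupper(need("common infos dataformat"))
  orient <- toupper(kv[["common infos dataorientation"]] %||% "MULTIPLEXED")
  data_file <- file.path(dirname(vhdr), need("common infos datafile"))

  labels <- character(n_chan)
  resolution <- rep(1, n_chan)
  for (i in seq_len(n_chan)) {
    entry <- channels[[paste0("Ch", i)]]
    if (is.null(entry)) {
      labels[i] <- paste0("ch", i)
    } else {
      parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
      labels[i] <- parts[1]
      if (length(parts) >= 3 && nzchar(parts[3])) {
        resolution[i] <- as.numeric(parts[3])
      }
    }
  }

  if (fmt == "BINARY") {
    bin_fmt <- toupper(kv[["binary infos binaryformat"]] %||% "IEEE_FLOAT_32")
    con <- file(data_file, "rb")
    on.exit(close(con))
    raw_n <- file.info(data_file)$size
    if (bin_fmt == "IEEE_FLOAT_32") {
      vals <- readBin(con, "numeric", n = raw_n / 4, size = 4,
                      endian = "little")
    } else if (bin_fmt %in% c("INT_16", "INT_32")) {
      sz <- if (bin_fmt == "INT_16") 2L else 4L
      vals <- readBin(con, "integer", n = raw_n / sz, size = sz,
                      signed = TRUE, endian = "little")
    } else {
      stop_ps(paste("unsupported binary format:", bin_fmt), "ps_bad_header")
    }
  } else if (fmt == "ASCII") {
    txt <- readLines(data_file, warn = FALSE)
    skip <- as.integer(kv[["ascii infos skiplines"]] %||% "0")
    if (skip > 0) txt <- txt[-seq_len(skip)]
    vals <- unlist(lapply(txt, function(l)
      as.numeric(strsplit(trimws(l), "[\\s]+", perl = TRUE)[[1]])))
  } else {
    stop_ps(paste("unsupported data format:", fmt), "ps_bad_header")
  }

  n_samp <- length(vals) %/% n_chan
  vals <- vals[seq_len(n_samp * n_chan)]
  data <- if (orient == "MULTIPLEXED") {
    matrix(vals, nrow = n_chan, ncol = n_samp)        # channel-fastest
  } else {
    t(matrix(vals, nrow = n_samp, ncol = n_chan))     # sample-fastest
  }
  data <- data * resolution
  eeg_recording(data, srate = srate, channel_labels = labels)
}

#' Write / read parcel time series as TSV
#'
#' Plain-text persistence: a comment line `# srate: <Hz>` followed by a
#' tab-separated table, one row per parcel, first column the parcel label.
#'
#' @param ts a [parcel_ts()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_parcel_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "parcel_ts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# srate: %.10g", ts$srate), con)
  df <- data.frame(parcel = ts$parcel_labels, ts$data,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_parcel_tsv
#' @param srate sampling rate override when the file lacks the comment.
#' @export
read_parcel_tsv <- function(path, srate = NULL) {
  first <- readLines(path, n = 1)
  if (grepl("^#\\s*srate:", first)) {
    srate <- as.numeric(sub("^#\\s*srate:\\s*", "", first))
    df <- utils::read.delim(path, header = FALSE, skip = 1,
                            comment.char = "")
  } else {
    if (is.null(srate)) stop_ps("srate not in file and not supplied",
                                "ps_bad_header")
    df <- utils::read.delim(path, header = FALSE, comment.char = "")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  parcel_ts(m, srate = srate, parcel_labels = as.character(df[[1]]))
}

#' Read a vertex-to-parcel map from two-column TSV
#'
#' @param path TSV with header columns `vertex_id`, `parcel_id`.
#' @return Integer parcel id vector ordered by vertex id.
#' @export
read_parcel_map <- function(path) {
  df <- utils::read.delim(path)
  stopifnot(all(c("vertex_id", "parcel_id") %in% names(df)))
  df <- df[order(df$vertex_id), ]
  as.integer(df$parcel_id)
}

#' Write a tidy table as TSV
#'
#' Thin wrapper used for coverage summaries, comparison tables, and edge
#' lists.
#'
#' @param x a data frame / tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a cleaned recording as TSV
#'
#' Plain-text persistence of a preprocessed recording: comment lines with
#' the sampling rate, reference, bad channels, and the artifact mask
#' (0/1 per sample), followed by one tab-separated row per channel.
#'
#' @param rec an [eeg_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_recording_tsv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# srate: %.10g", rec$srate),
    sprintf("# reference: %s", rec$reference),
    sprintf("# bad_channels: %s", paste(rec$bad_channels, collapse = ",")),
    sprintf("# artifact_mask: %s",
            paste(as.integer(rec$artifact_mask), collapse = ""))), con)
  df <- data.frame(channel = rec$channel_labels, rec$data,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_tsv
#' @export
read_recording_tsv <- function(path) {
  hdr <- readLines(path, n = 4)
  get <- function(key) sub(paste0("^#\\s*", key, ":\\s*"), "",
                           hdr[grepl(paste0("^#\\s*", key, ":"), hdr)])
  srate <- as.numeric(get("srate"))
  reference <- get("reference")
  bad <- get("bad_channels")
  bad <- if (nzchar(bad)) strsplit(bad, ",")[[1]] else character()
  mask <- as.logical(as.integer(strsplit(get("artifact_mask"), "")[[1]]))
  df <- utils::read.delim(path, header = FALSE, skip = 4, comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  eeg_recording(m, srate = srate, channel_labels = as.character(df[[1]]),
                reference = reference, bad_channels = bad,
                artifact_mask = mask)
}
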