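#' Write / read tone-onset event tables
#'
#' Tab-separated UTF-8 with a header row; onsets in ms as decimals. The
#' reader validates the schema and that onsets are strictly increasing per
#' performer within a condition, reporting the offending row.
#'
#' @param trials an event tibble (see [simulate_duet_timing()])
#' @param path file path
#' @return `read_events()` returns the tibble; `write_events()` its path,
#'   invisibly
#' @export
write_events <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  required <- c("pair_id", "performer", "condition", "repetition",
                "event_index", "nominal_pitch", "played_pitch",
                "onset_ms", "beat_value", "is_on_beat")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("event table lacks column(s): ", paste(missing, collapse = ", "))
  }
  key <- interaction(tab$performer, tab$condition, drop = TRUE)
  for (piece in split(seq_len(nrow(tab)), key)) {
    d <- diff(tab$onset_ms[piece])
    if (any(d <= 0)) {
      stop(sprintf("onsets not strictly increasing at row %d",
                   piece[which(d <= 0)[1] + 1]))
    }
  }
  tibble::as_tibble(tab)
}

#' Write / read EEG recordings (flat binary + JSON sidecar)
#'
#' The native on-disk format is a flat little-endian float64 binary of the
#' channels-by-samples matrix (channel-major) plus a JSON sidecar holding
#' the sampling rate, channel names, dimensions, and event anchors. The
#' round trip is exact.
#'
#' @param recording an [eeg_recording()]
#' @param path path of the binary file; the sidecar is `<path>.json`
#' @return `read_eeg()` returns the recording; `write_eeg()` the path,
#'   invisibly
#' @export
write_eeg <- function(recording, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(recording$data)), con, size = 8, endian = "little")
  meta <- list(fs = recording$fs,
               channel_names = recording$channel_names,
               n_channels = nrow(recording$data),
               n_samples = ncol(recording$data),
               anchors = recording$anchors)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_eeg
#' @export
read_eeg <- function(path) {
  if (grepl("\\.(edf|xdf)$", tolower(path))) {
    stop("unsupported format: ", path, " (native flat binary + JSON only)")
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  dat <- matrix(x, nrow = meta$n_channels, byrow = TRUE)
  anchors <- if (!is.null(meta$anchors) && length(meta$anchors)) {
    tibble::as_tibble(meta$anchors)
  } else NULL
  eeg_recording(dat, meta$fs, meta$channel_names, anchors)
}
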