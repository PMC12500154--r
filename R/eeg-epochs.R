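#' Epoched EEG container
#'
#' Trials x channels x time array of voltages (microvolt) with channel
#' names, sampling rate, a cue-locked millisecond time axis, and per-trial
#' metadata. The lateralized (N2pc) operations require the posterior pair
#' PO7/PO8 and per-trial `cued_side` metadata.
#'
#' @param data numeric array, trials x channels x time.
#' @param channels character vector of unique channel names.
#' @param rate sampling rate in Hz.
#' @param time_ms time axis in ms (cue at 0).
#' @param metadata tibble with one row per trial, containing `trial_id`.
#' @return an object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, channels, rate, time_ms, metadata) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[2] == length(channels),
            dim(data)[3] == length(time_ms),
            !anyDuplicated(channels),
            rate > 0)
  metadata <- as_tibble(metadata)
  if (!"trial_id" %in% names(metadata) || nrow(metadata) != dim(data)[1])
    stop("metadata needs a trial_id column and one row per trial",
         call. = FALSE)
  dimnames(data) <- list(NULL, channels, NULL)
  structure(list(data = data, channels = channels, rate = rate,
                 time_ms = as.numeric(time_ms), metadata = metadata),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat("<eeg_epochs> ", dim(x$data)[1], " trials x ", dim(x$data)[2],
      " channels x ", dim(x$data)[3], " samples (", x$rate, " Hz; ",
      paste(x$channels, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Subset an EEG epochs object by trial
#'
#' @param ep an [eeg_epochs] object.
#' @param trials logical or integer index over trials.
#' @return an [eeg_epochs] with the selected trials.
#' @export
subset_trials <- function(ep, trials) {
  eeg_epochs(ep$data[trials, , , drop = FALSE], ep$channels, ep$rate,
             ep$time_ms, ep$metadata[trials, , drop = FALSE])
}

#' Baseline-correct epoched EEG
#'
#' Subtracts, per trial and channel, the mean potential over the pre-cue
#' baseline window (default the 250 ms preceding cue onset, `[-250, 0)`).
#' After correction the baseline mean is zero up to floating-point
#' tolerance; the operation is idempotent.
#'
#' @param ep an [eeg_epochs] object.
#' @param window baseline window in ms, half-open (default `c(-250, 0)`).
#' @return the corrected [eeg_epochs].
#' @export
baseline_correct <- function(ep, window = c(-250, 0)) {
  stop_if_not_window(window, range(ep$time_ms) + c(0, 1), "baseline window")
  idx <- window_idx(ep$time_ms, window)
  if (!length(idx)) stop("baseline window contains no samples", call. = FALSE)
  m <- apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - array(m, dim(ep$data))
  ep
}

#' Read and write epoched EEG as a portable array container
#'
#' The on-disk format is a raw little-endian float64 stream (`<prefix>.bin`,
#' trials varying slowest, then channels, then time) plus a JSON sidecar
#' (`<prefix>.json`) holding the dimensions, channel names, sampling rate,
#' time axis and trial metadata. The round trip is lossless.
#'
#' @param ep an [eeg_epochs] object.
#' @param prefix file path without extension.
#' @return `write_eeg_epochs()` returns `prefix` invisibly;
#'   `read_eeg_epochs()` returns an [eeg_epochs].
#' @export
write_eeg_epochs <- function(ep, prefix) {
  # aperm so that time varies fastest in the stream
  vec <- as.vector(aperm(ep$data, c(3, 2, 1)))
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(vec, con, size = 8, endian = "little")
  side <- list(dims = dim(ep$data), channels = ep$channels, rate = ep$rate,
               time_ms = ep$time_ms, metadata = ep$metadata)
  jsonlite::write_json(side, paste0(prefix, ".json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(prefix)
}

#' @rdname write_eeg_epochs
#' @export
read_eeg_epochs <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  dims <- as.integer(side$dims)
  n <- prod(dims)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  vec <- readBin(con, what = "double", n = n, size = 8, endian = "little")
  data <- aperm(array(vec, dim = dims[c(3, 2, 1)]), c(3, 2, 1))
  eeg_epochs(data, side$channels, side$rate, side$time_ms,
             as_tibble(side$metadata))
}
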