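#' Gaze epochs container
#'
#' Holds cue-locked gaze traces for a set of trials: horizontal and vertical
#' position (visual degrees) as trials x time matrices on a uniform
#' millisecond time axis, plus per-trial metadata. Missing samples (masked
#' blinks, signal loss) are `NA`. Epochs follow the half-open time
#' convention `[window[1], window[2])` with the attention cue at 0 ms.
#'
#' @param x,y numeric matrices, trials x samples, in visual degrees.
#' @param time_ms numeric vector of sample times (ms, uniform spacing).
#' @param metadata tibble with one row per trial; must contain `trial_id`;
#'   typically also `task`, `cued_side` ("left"/"right"), `participant`.
#' @return an object of class `gaze_epochs`.
#' @export
gaze_epochs <- function(x, y, time_ms, metadata) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(identical(dim(x), dim(y)), ncol(x) == length(time_ms))
  metadata <- as_tibble(metadata)
  if (!"trial_id" %in% names(metadata))
    stop("metadata must contain a trial_id column", call. = FALSE)
  if (nrow(metadata) != nrow(x))
    stop("metadata rows must match the number of trials", call. = FALSE)
  d <- diff(time_ms)
  if (length(d) && (any(d <= 0) || diff(range(d)) > 1e-6))
    stop("time axis must be strictly increasing and uniform", call. = FALSE)
  structure(
    list(x = x, y = y, time_ms = as.numeric(time_ms), metadata = metadata),
    class = "gaze_epochs"
  )
}

#' @export
print.gaze_epochs <- function(x, ...) {
  cat("<gaze_epochs> ", nrow(x$x), " trials x ", ncol(x$x), " samples (",
      x$time_ms[1], "..", x$time_ms[length(x$time_ms)], " ms, ",
      round(gaze_rate(x)), " Hz)\n", sep = "")
  invisible(x)
}

gaze_rate <- function(ge) 1000 / diff(ge$time_ms[1:2])

#' @export
#' @method as_tibble gaze_epochs
as_tibble.gaze_epochs <- function(x, ...) {
  nt <- nrow(x$x); ns <- ncol(x$x)
  out <- tibble(
    trial_id = rep(x$metadata$trial_id, each = ns),
    time_ms = rep(x$time_ms, times = nt),
    x_deg = as.vector(t(x$x)),
    y_deg = as.vector(t(x$y))
  )
  extra <- setdiff(names(x$metadata), "trial_id")
  if (length(extra))
    out <- left_join(out, x$metadata, by = "trial_id")
  out
}

#' Mask blinks in gaze traces
#'
#' Eye-tracker signal loss during blinks is encoded as zero samples on both
#' gaze axes. Every run of consecutive zero samples, padded by `pad_ms`
#' before its first and after its last sample, is set to missing (`NA`) on
#' both axes; padded spans that overlap merge into one missing span. No
#' other samples are altered and the operation is idempotent. An all-zero
#' trial becomes fully missing (flagged, not an error).
#'
#' @param x horizontal gaze samples (degrees) or a [gaze_epochs] object.
#' @param y vertical gaze samples; ignored for the `gaze_epochs` method.
#' @param pad_ms padding applied on each side of a zero run (default 100 ms).
#' @param rate sampling rate in Hz (default 1000).
#' @return for vectors, a list with masked `x` and `y`; for `gaze_epochs`,
#'   a masked `gaze_epochs` object.
#' @export
mask_blinks <- function(x, ...) UseMethod("mask_blinks")

#' @rdname mask_blinks
#' @export
mask_blinks.default <- function(x, y, pad_ms = 100, rate = 1000, ...) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  zero <- !is.na(x) & !is.na(y) & x == 0 & y == 0
  if (any(zero)) {
    pad <- round(pad_ms * rate / 1000)
    r <- rle(zero)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bad <- rep(FALSE, n)
    for (i in which(r$values)) {
      lo <- max(1L, starts[i] - pad)
      hi <- min(n, ends[i] + pad)
      bad[lo:hi] <- TRUE
    }
    x[bad] <- NA_real_
    y[bad] <- NA_real_
  }
  list(x = x, y = y)
}

#' @rdname mask_blinks
#' @export
mask_blinks.gaze_epochs <- function(x, pad_ms = 100, ...) {
  rate <- gaze_rate(x)
  for (i in seq_len(nrow(x$x))) {
    m <- mask_blinks.default(x$x[i, ], x$y[i, ], pad_ms = pad_ms, rate = rate)
    x$x[i, ] <- m$x
    x$y[i, ] <- m$y
  }
  x
}

#' Epoch a continuous gaze recording around cue onsets
#'
#' Cuts fixed-length epochs `[cue + window[1], cue + window[2])` out of a
#' continuous recording. Cues whose epoch would extend beyond the recording
#' are skipped and reported (with a reason) in the `skipped` attribute.
#'
#' @param samples tibble with columns `time_ms`, `x_deg`, `y_deg`
#'   (uniformly sampled continuous recording).
#' @param cue_onsets cue times in ms (same clock as `samples$time_ms`).
#' @param window length-2 epoch window in ms relative to cue
#'   (default `c(-1000, 1500)`).
#' @return a [gaze_epochs] object with one trial per retained cue (time axis
#'   relative to cue); attribute `"skipped"` is a tibble of rejected cues.
#' @export
epoch_gaze <- function(samples, cue_onsets, window = c(-1000, 1500)) {
  stopifnot(all(c("time_ms", "x_deg", "y_deg") %in% names(samples)))
  tm <- samples$time_ms
  step <- diff(tm[1:2])
  n_out <- round((window[2] - window[1]) / step)
  keep <- list(); skipped <- list()
  for (cue in cue_onsets) {
    i0 <- round((cue + window[1] - tm[1]) / step) + 1
    i1 <- i0 + n_out - 1
    if (i0 < 1 || i1 > length(tm)) {
      skipped[[length(skipped) + 1]] <-
        tibble(cue_ms = cue,
               reason = if (i0 < 1) "window underflows recording"
                        else "window overflows recording")
    } else {
      keep[[length(keep) + 1]] <- list(cue = cue, idx = i0:i1)
    }
  }
  time_rel <- window[1] + (seq_len(n_out) - 1) * step
  xm <- do.call(rbind, lapply(keep, function(k) samples$x_deg[k$idx]))
  ym <- do.call(rbind, lapply(keep, function(k) samples$y_deg[k$idx]))
  if (is.null(xm)) {
    xm <- matrix(numeric(), 0, n_out)
    ym <- matrix(numeric(), 0, n_out)
  }
  md <- tibble(trial_id = seq_along(keep),
               cue_ms = vapply(keep, function(k) k$cue, numeric(1)))
  out <- gaze_epochs(xm, ym, time_rel, md)
  attr(out, "skipped") <- if (length(skipped)) bind_rows(skipped)
                          else tibble(cue_ms = numeric(), reason = character())
  out
}

#' Read and write delimited gaze tables
#'
#' The on-disk gaze format is a plain CSV in long form with columns
#' `trial_id`, `task`, `time_ms`, `x_deg`, `y_deg`. `read_gaze_table()`
#' validates the column set and per-trial sampling uniformity and rebuilds a
#' [gaze_epochs] object; trial metadata (e.g. `cued_side`) can be joined in
#' from a metadata table.
#'
#' @param path file path.
#' @param metadata optional tibble keyed by `trial_id` to join into the
#'   epochs' metadata.
#' @return `read_gaze_table()` returns a [gaze_epochs]; `write_gaze_table()`
#'   returns `path` invisibly.
#' @export
read_gaze_table <- function(path, metadata = NULL) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("trial_id", "task", "time_ms", "x_deg", "y_deg")
  if (!all(need %in% names(tbl)))
    stop("gaze table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ids <- unique(tbl$trial_id)
  tm <- tbl$time_ms[tbl$trial_id == ids[1]]
  ns <- length(tm)
  xm <- matrix(NA_real_, length(ids), ns)
  ym <- matrix(NA_real_, length(ids), ns)
  for (i in seq_along(ids)) {
    sub <- tbl[tbl$trial_id == ids[i], ]
    if (nrow(sub) != ns || any(abs(sub$time_ms - tm) > 1e-6))
      stop("trial ", ids[i], " has a non-matching time axis", call. = FALSE)
    xm[i, ] <- sub$x_deg
    ym[i, ] <- sub$y_deg
  }
  md <- dplyr::distinct(tbl[, c("trial_id", "task")])
  if (!is.null(metadata))
    md <- left_join(md, metadata, by = intersect(names(md), names(metadata)))
  gaze_epochs(xm, ym, tm, md)
}

#' @rdname read_gaze_table
#' @param ge a [gaze_epochs] object.
#' @export
write_gaze_table <- function(ge, path) {
  tbl <- as_tibble(ge)
  cols <- intersect(c("trial_id", "task", "time_ms", "x_deg", "y_deg"),
                    names(tbl))
  readr::write_csv(tbl[, cols], path, progress = FALSE)
  invisible(path)
}
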