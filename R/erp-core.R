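#' Contralateral / ipsilateral event-related potentials
#'
#' Builds the lateralized ERP for a symmetric posterior channel pair
#' (default PO7/PO8) relative to the (memorized) location of the cued
#' object: the contralateral wave averages the right-hemisphere channel on
#' left-cued trials and the left-hemisphere channel on right-cued trials
#' (the ipsilateral wave symmetrically), pooling trials. The trial-averaged
#' waves are smoothed with a Gaussian kernel (default SD 15 samples,
#' reflective edge padding) and the difference wave `contra - ipsi` carries
#' the N2pc.
#'
#' @param ep a baseline-corrected [eeg_epochs] whose metadata carries
#'   `cued_side`.
#' @param pair channel pair `c(left_hemisphere, right_hemisphere)`, default
#'   `c("PO7", "PO8")`.
#' @param smooth_sd Gaussian smoothing SD in samples (default 15); 0
#'   disables smoothing.
#' @return a `lateralized_wave` tibble: `time_ms`, `contra`, `ipsi`,
#'   `diff` (microvolt), with attributes `n_left`, `n_right`, `smooth_sd`.
#' @export
contra_ipsi <- function(ep, pair = c("PO7", "PO8"), smooth_sd = 15) {
  if (!all(pair %in% ep$channels))
    stop("channels ", paste(setdiff(pair, ep$channels), collapse = ", "),
         " not present", call. = FALSE)
  side <- ep$metadata$cued_side
  if (is.null(side) || any(!side %in% c("left", "right")))
    stop("metadata must carry cued_side ('left'/'right')", call. = FALSE)
  iL <- which(side == "left"); iR <- which(side == "right")
  if (!length(iL)) stop("no left-cued trials", call. = FALSE)
  if (!length(iR)) stop("no right-cued trials", call. = FALSE)
  chL <- match(pair[1], ep$channels)
  chR <- match(pair[2], ep$channels)
  # pooled trial means: contra = {right ch | left cue} + {left ch | right cue}
  sum_contra <- colSums(ch_slice(ep, iL, chR)) + colSums(ch_slice(ep, iR, chL))
  sum_ipsi <- colSums(ch_slice(ep, iL, chL)) + colSums(ch_slice(ep, iR, chR))
  n <- length(iL) + length(iR)
  contra <- sum_contra / n
  ipsi <- sum_ipsi / n
  if (smooth_sd > 0) {
    contra <- smooth_gaussian(contra, smooth_sd, pad = "reflect")
    ipsi <- smooth_gaussian(ipsi, smooth_sd, pad = "reflect")
  }
  out <- tibble(time_ms = ep$time_ms, contra = contra, ipsi = ipsi,
                diff = contra - ipsi)
  attr(out, "n_left") <- length(iL)
  attr(out, "n_right") <- length(iR)
  attr(out, "smooth_sd") <- smooth_sd
  class(out) <- c("lateralized_wave", class(out))
  out
}

# trials x time matrix for one channel (robust to single-trial subsets)
ch_slice <- function(ep, trials, ch) {
  s <- ep$data[trials, ch, , drop = FALSE]
  dim(s) <- c(length(trials), dim(ep$data)[3])
  s
}

#' Per-trial lateralized difference series
#'
#' For single-trial analyses (ERP images) each trial's contralateral-minus-
#' ipsilateral series is needed rather than the trial average: on left-cued
#' trials `pair[2] - pair[1]`, on right-cued trials `pair[1] - pair[2]`.
#'
#' @inheritParams contra_ipsi
#' @return trials x time matrix of difference voltages.
#' @export
trialwise_diff <- function(ep, pair = c("PO7", "PO8")) {
  chL <- match(pair[1], ep$channels)
  chR <- match(pair[2], ep$channels)
  if (anyNA(c(chL, chR))) stop("channel pair not present", call. = FALSE)
  side <- ep$metadata$cued_side
  sgn <- ifelse(side == "left", 1, -1)
  d <- ep$data[, chR, , drop = TRUE] - ep$data[, chL, , drop = TRUE]
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  d * sgn
}

#' Grand average of lateralized waves
#'
#' Unweighted mean across participants of per-participant lateralized
#' waves (participants first, then the grand mean — so each participant
#' contributes equally regardless of trial counts).
#'
#' @param waves list of `lateralized_wave` tibbles on a common time axis.
#' @return a `lateralized_wave` tibble.
#' @export
grand_average <- function(waves) {
  stopifnot(length(waves) >= 1)
  tm <- waves[[1]]$time_ms
  acc <- function(col) rowMeans(vapply(waves, function(w) w[[col]],
                                       numeric(length(tm))))
  out <- tibble(time_ms = tm, contra = acc("contra"), ipsi = acc("ipsi"),
                diff = acc("diff"))
  class(out) <- c("lateralized_wave", class(out))
  out
}

#' Windowed N2pc amplitude
#'
#' Mean of the contralateral-minus-ipsilateral difference wave over the
#' a-priori N2pc window (default `[200, 300)` ms after cue onset), in
#' microvolt. Linear in the wave: scaling the wave scales the amplitude.
#'
#' @param wave a `lateralized_wave` tibble.
#' @param window amplitude window in ms, half-open (default `c(200, 300)`).
#' @return scalar amplitude in microvolt.
#' @export
n2pc_amplitude <- function(wave, window = c(200, 300)) {
  rng <- range(wave$time_ms)
  stop_if_not_window(window, rng + c(0, diff(wave$time_ms[1:2])),
                     "N2pc window")
  idx <- window_idx(wave$time_ms, window)
  mean(wave$diff[idx])
}
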