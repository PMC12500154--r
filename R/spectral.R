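#' Short-time Fourier power
#'
#' Sliding-window spectral power per trial and channel: each 300-ms segment
#' is Hanning-tapered, zero-padded to one second of samples (a power of two
#' at 1024 Hz, giving exact integer-Hz frequency bins), and Fourier
#' transformed; power is the squared magnitude at the requested integer
#' frequencies. Time stamps are segment centers, advanced in `step_ms`
#' steps over the part of the epoch where the full window fits.
#'
#' @param ep an [eeg_epochs] object.
#' @param window_ms taper window length in ms (default 300).
#' @param step_ms step between segment centers (default 20).
#' @param freqs requested frequencies in Hz (default `3:40`); must not
#'   exceed Nyquist.
#' @return a `tfr_power` object: power array trials x channels x freq x
#'   time plus axes and the trial metadata.
#' @export
stft_power <- function(ep, window_ms = 300, step_ms = 20, freqs = 3:40) {
  if (max(freqs) > ep$rate / 2)
    stop("requested frequency above Nyquist (", ep$rate / 2, " Hz)",
         call. = FALSE)
  L <- round(window_ms * ep$rate / 1000)
  if (dim(ep$data)[3] < L)
    stop("epoch shorter than the STFT window", call. = FALSE)
  nfft <- max(2^ceiling(log2(L)), ep$rate)  # one second at integer rates
  df <- ep$rate / nfft
  bins <- round(freqs / df) + 1L
  if (any(abs(bins - 1 - freqs / df) > 1e-9))
    warning("requested frequencies are off the FFT grid; nearest bins used")
  taper <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / (L - 1)))
  nt <- dim(ep$data)[1]; nc <- dim(ep$data)[2]; ns <- dim(ep$data)[3]
  half <- (L - 1) / 2
  starts <- seq(1, ns - L + 1, by = round(step_ms * ep$rate / 1000))
  centers <- ep$time_ms[round(starts + half)]
  pw <- array(NA_real_, c(nt, nc, length(freqs), length(starts)))
  segmat <- matrix(0, nfft, nt * nc)
  for (si in seq_along(starts)) {
    seg <- ep$data[, , starts[si] + 0:(L - 1), drop = FALSE]
    # reshape to L x (trials*channels), taper, pad, transform
    segmat[seq_len(L), ] <- t(matrix(seg, nt * nc, L)) * taper
    sp <- stats::mvfft(segmat)[bins, , drop = FALSE]
    pw[, , , si] <- array(t(Mod(sp)^2), c(nt, nc, length(freqs)))
  }
  structure(list(power = pw, freqs = freqs, time_ms = centers,
                 channels = ep$channels, rate = ep$rate,
                 metadata = ep$metadata),
            class = "tfr_power")
}

#' @export
print.tfr_power <- function(x, ...) {
  cat("<tfr_power> ", dim(x$power)[1], " trials x ", dim(x$power)[2],
      " channels x ", length(x$freqs), " freqs x ", length(x$time_ms),
      " times\n", sep = "")
  invisible(x)
}

#' Contralateral/ipsilateral spectral lateralization index
#'
#' Power is first averaged over trials within each cued side (ratio of
#' means, stabler than mean of ratios at low trial counts), assembled into
#' contralateral and ipsilateral time-frequency maps for the channel pair,
#' and expressed as the bounded percent asymmetry
#' `L = (contra - ipsi) / (contra + ipsi) * 100`. Cells with zero total
#' power are undefined (`NA`) and excluded from summaries.
#'
#' @param tfr a `tfr_power` object from [stft_power()].
#' @param pair channel pair `c(left_hemisphere, right_hemisphere)`.
#' @return a `tfr_lat` tibble: `freq`, `time_ms`, `contra`, `ipsi`, `lat`
#'   (percent, in `[-100, 100]`).
#' @export
lateralization_index <- function(tfr, pair = c("PO7", "PO8")) {
  chL <- match(pair[1], tfr$channels)
  chR <- match(pair[2], tfr$channels)
  if (anyNA(c(chL, chR))) stop("channel pair not present", call. = FALSE)
  side <- tfr$metadata$cued_side
  if (is.null(side)) stop("metadata must carry cued_side", call. = FALSE)
  iL <- which(side == "left"); iR <- which(side == "right")
  if (!length(iL) || !length(iR))
    stop("both cued sides must be represented", call. = FALSE)
  msl <- function(trials, ch) {
    s <- tfr$power[trials, ch, , , drop = FALSE]
    colMeans(array(s, c(length(trials), length(tfr$freqs),
                        length(tfr$time_ms))))
  }
  nL <- length(iL); nR <- length(iR)
  contra <- (msl(iL, chR) * nL + msl(iR, chL) * nR) / (nL + nR)
  ipsi <- (msl(iL, chL) * nL + msl(iR, chR) * nR) / (nL + nR)
  lat <- 100 * (contra - ipsi) / (contra + ipsi)
  lat[(contra + ipsi) == 0] <- NA_real_
  out <- tibble(
    freq = rep(tfr$freqs, times = length(tfr$time_ms)),
    time_ms = rep(tfr$time_ms, each = length(tfr$freqs)),
    contra = as.vector(contra), ipsi = as.vector(ipsi),
    lat = as.vector(lat)
  )
  class(out) <- c("tfr_lat", class(out))
  out
}

#' Alpha-band lateralization summary
#'
#' Mean lateralization index over the alpha band and post-cue summary
#' window (defaults 8-12 Hz and 400-800 ms). Undefined cells are excluded.
#'
#' @param lat a `tfr_lat` tibble from [lateralization_index()].
#' @param freq_band inclusive frequency band in Hz (default `c(8, 12)`).
#' @param time_window inclusive time window in ms (default `c(400, 800)`).
#' @return scalar mean lateralization (percent).
#' @export
alpha_lateralization <- function(lat, freq_band = c(8, 12),
                                 time_window = c(400, 800)) {
  sel <- lat$freq >= freq_band[1] & lat$freq <= freq_band[2] &
    lat$time_ms >= time_window[1] & lat$time_ms <= time_window[2]
  mean(lat$lat[sel], na.rm = TRUE)
}
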