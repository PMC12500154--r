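#' Detection parameters for velocity-threshold microsaccade detection
#'
#' Defaults follow the standard median-velocity procedure: threshold at
#' `k_threshold` times the trial median of the smoothed gaze velocity,
#' velocity smoothed with a Gaussian-weighted moving average over a 7-ms
#' window, a 100-ms onset-to-onset refractory period, direction and
#' magnitude from mean gaze position in a pre-onset window (-50..0 ms) vs a
#' post-onset window (50..100 ms), and a minimum magnitude of 0.05 degrees
#' (shifts below it are recorded but not counted as saccades).
#'
#' @param k_threshold velocity-threshold multiplier of the median (default 3).
#' @param smooth_window_ms width of the Gaussian smoothing window (default 7).
#' @param refractory_ms minimum onset-to-onset delay between events
#'   (default 100).
#' @param pre_window_ms,post_window_ms characterization windows in ms
#'   relative to onset, half-open.
#' @param min_magnitude_deg minimum accepted shift magnitude (default 0.05).
#' @param mode `"1d"` (horizontal channel only) or `"2d"` (horizontal and
#'   vertical combined).
#' @return a `detect_params` list.
#' @export
detect_params <- function(k_threshold = 3,
                          smooth_window_ms = 7,
                          refractory_ms = 100,
                          pre_window_ms = c(-50, 0),
                          post_window_ms = c(50, 100),
                          min_magnitude_deg = 0.05,
                          mode = c("1d", "2d")) {
  mode <- match.arg(mode)
  stopifnot(k_threshold > 0, smooth_window_ms > 0, refractory_ms > 0,
            min_magnitude_deg > 0,
            pre_window_ms[1] < pre_window_ms[2],
            post_window_ms[1] < post_window_ms[2])
  structure(list(k_threshold = k_threshold,
                 smooth_window_ms = smooth_window_ms,
                 refractory_ms = refractory_ms,
                 pre_window_ms = pre_window_ms,
                 post_window_ms = post_window_ms,
                 min_magnitude_deg = min_magnitude_deg,
                 mode = mode),
            class = "detect_params")
}

#' Sample-to-sample gaze velocity
#'
#' Velocity is the Euclidean distance between temporally successive gaze
#' positions divided by the sample interval, in degrees per second. In
#' `"1d"` mode only the horizontal channel enters; in `"2d"` mode the step
#' length combines horizontal and vertical components. The velocity at
#' sample `i` describes the step from sample `i - 1` to `i` (aligned to the
#' later sample); the first sample is `NA`, as is any step touching a
#' missing position sample.
#'
#' @param ge a [gaze_epochs] object.
#' @param mode `"1d"` or `"2d"`.
#' @return trials x samples matrix of velocities (deg/s); column 1 is `NA`.
#' @export
compute_velocity <- function(ge, mode = c("1d", "2d")) {
  mode <- match.arg(mode)
  rate <- gaze_rate(ge)
  ns <- ncol(ge$x)
  dx <- cbind(NA_real_, ge$x[, -1, drop = FALSE] -
                ge$x[, -ns, drop = FALSE])
  if (mode == "1d") {
    v <- abs(dx) * rate
  } else {
    dy <- cbind(NA_real_, ge$y[, -1, drop = FALSE] -
                  ge$y[, -ns, drop = FALSE])
    v <- sqrt(dx^2 + dy^2) * rate
  }
  v
}

#' Smooth a velocity trace
#'
#' Gaussian-weighted moving average over a window of `window_ms`
#' milliseconds (7 ms at 1 kHz = 7 samples by default). Missing samples are
#' excluded from the average with weight renormalization, so gaps neither
#' propagate nor bias neighbouring samples; output length equals input
#' length. The kernel standard deviation is `(window - 1) / 5` samples,
#' the convention of common gaussian-window smoothers.
#'
#' @param v numeric vector or trials x samples matrix of velocities.
#' @param window_ms smoothing window width in ms.
#' @param rate sampling rate in Hz.
#' @return smoothed velocities, same shape as `v`.
#' @export
smooth_velocity <- function(v, window_ms = 7, rate = 1000) {
  w <- max(3L, round(window_ms * rate / 1000))
  if (w %% 2 == 0) w <- w + 1L
  sd <- (w - 1) / 5
  radius <- (w - 1L) %/% 2L
  if (is.matrix(v)) smooth_rows(v, sd = sd, radius = radius, pad = "renorm")
  else smooth_gaussian(v, sd = sd, radius = radius, pad = "renorm")
}

# Characterize one candidate onset; returns a one-row tibble or NULL when
# the pre/post windows are truncated by the epoch edge or fully missing.
characterize_event <- function(ge, trial_row, onset_idx, params, rate) {
  time <- ge$time_ms
  onset_ms <- time[onset_idx]
  step <- 1000 / rate
  ns <- length(time)
  # arithmetic half-open sample windows on the uniform time axis
  rng <- function(w) {
    i0 <- onset_idx + ceiling(w[1] / step - 1e-9)
    i1 <- onset_idx + ceiling(w[2] / step - 1e-9) - 1L
    if (i0 < 1 || i1 > ns) NULL else i0:i1
  }
  pre_i <- rng(params$pre_window_ms)
  post_i <- rng(params$post_window_ms)
  if (is.null(pre_i) || is.null(post_i))
    return(list(reason = "characterization window truncated"))
  x_pre <- mean(ge$x[trial_row, pre_i], na.rm = TRUE)
  x_post <- mean(ge$x[trial_row, post_i], na.rm = TRUE)
  if (!is.finite(x_pre) || !is.finite(x_post))
    return(list(reason = "characterization window missing"))
  dx <- x_post - x_pre
  if (params$mode == "2d") {
    y_pre <- mean(ge$y[trial_row, pre_i], na.rm = TRUE)
    y_post <- mean(ge$y[trial_row, post_i], na.rm = TRUE)
    if (!is.finite(y_pre) || !is.finite(y_post))
      return(list(reason = "characterization window missing"))
    dy <- y_post - y_pre
    mag <- sqrt(dx^2 + dy^2)
    ang <- atan2(dy, dx)
  } else {
    mag <- abs(dx)
    ang <- NA_real_
  }
  list(onset_ms = onset_ms, direction = if (dx < 0) -1 else 1,
       angle = ang, magnitude_deg = mag)
}

#' Detect (micro)saccades by median-velocity thresholding
#'
#' Per trial, the smoothed gaze velocity is compared against a trial-based
#' threshold of `k_threshold` times the median of the trial's valid smoothed
#' velocity samples. The first sample of each supra-threshold crossing marks
#' a candidate onset; onsets within `refractory_ms` of an accepted onset are
#' discarded so the same saccade is not counted twice. Each accepted onset
#' is characterized by comparing mean gaze position in the pre-onset window
#' with the post-onset window: the sign of the difference gives the
#' direction (-1 left, +1 right), its absolute value the magnitude (in 2d
#' mode, vector angle and norm). Shifts smaller than `min_magnitude_deg`
#' are kept in the table with `status = "sub_minimum"` so that trial
#' classification can exclude those trials; events whose characterization
#' windows are truncated by the epoch edge or fully missing get
#' `status = "unresolved"`.
#'
#' @param ge a [gaze_epochs] object (blink-masked).
#' @param params a [detect_params] list.
#' @return tibble with columns `trial_id`, `onset_ms`, `direction`, `angle`,
#'   `magnitude_deg`, `peak_velocity`, `status` (`"ok"`, `"sub_minimum"`, or
#'   `"unresolved"`). Use [saccade_events()] for accepted events only.
#' @export
detect_saccades <- function(ge, params = detect_params()) {
  stopifnot(inherits(ge, "gaze_epochs"))
  rate <- gaze_rate(ge)
  ns <- ncol(ge$x)
  # per-trial smoother with precomputed edge renormalization for the
  # common gap-free case
  wlen <- max(3L, round(params$smooth_window_ms * rate / 1000))
  if (wlen %% 2 == 0) wlen <- wlen + 1L
  ksd <- (wlen - 1) / 5
  krad <- (wlen - 1L) %/% 2L
  kern <- gaussian_kernel(ksd, krad)
  nv <- ns - 1L  # velocity samples (one per position step)
  zp <- rep(0, krad)
  sel <- krad + seq_len(nv)
  den_clean <- as.numeric(stats::filter(c(zp, rep(1, nv), zp), kern,
                                        sides = 2)[sel])
  smooth1 <- function(v) {
    if (anyNA(v)) smooth_gaussian(v, ksd, krad, "renorm")
    else as.numeric(stats::filter(c(zp, v, zp), kern,
                                  sides = 2)[sel]) / den_clean
  }
  refr <- params$refractory_ms
  acc <- list(trial_id = list(), onset_ms = list(), direction = list(),
              angle = list(), magnitude_deg = list(),
              peak_velocity = list(), status = list())
  for (i in seq_len(nrow(ge$x))) {
    xr <- ge$x[i, ]
    dxr <- xr[-1] - xr[-ns]
    if (params$mode == "1d") {
      vi <- abs(dxr) * rate
    } else {
      yr <- ge$y[i, ]
      dyr <- yr[-1] - yr[-ns]
      vi <- sqrt(dxr^2 + dyr^2) * rate
    }
    if (all(is.na(vi))) next
    vi <- smooth1(vi)
    valid <- which(!is.na(vi))
    if (length(valid) < 1) next
    thr <- params$k_threshold * median(vi[valid])
    above <- !is.na(vi) & vi > thr
    # first sample of each crossing: above with the previous sample not above
    prev <- c(FALSE, above[-length(above)])
    cand <- which(above & !prev)
    if (!length(cand)) next
    last_on <- -Inf
    for (cv in cand) {
      ci <- cv + 1L  # velocity sample cv describes the step into sample cv+1
      t_ci <- ge$time_ms[ci]
      if (t_ci - last_on < refr) next
      last_on <- t_ci
      ch <- characterize_event(ge, i, ci, params, rate)
      j <- length(acc$onset_ms) + 1L
      acc$trial_id[[j]] <- ge$metadata$trial_id[i]
      acc$onset_ms[[j]] <- t_ci
      if (!is.null(ch$reason)) {
        acc$direction[[j]] <- NA_real_
        acc$angle[[j]] <- NA_real_
        acc$magnitude_deg[[j]] <- NA_real_
        acc$peak_velocity[[j]] <- NA_real_
        acc$status[[j]] <- "unresolved"
        next
      }
      run_end <- cv
      while (run_end < length(above) && above[run_end + 1]) run_end <- run_end + 1
      acc$direction[[j]] <- ch$direction
      acc$angle[[j]] <- ch$angle
      acc$magnitude_deg[[j]] <- ch$magnitude_deg
      acc$peak_velocity[[j]] <- max(vi[cv:run_end], na.rm = TRUE)
      acc$status[[j]] <- if (ch$magnitude_deg < params$min_magnitude_deg)
        "sub_minimum" else "ok"
    }
  }
  tibble(
    trial_id = unlist(acc$trial_id) %||% ge$metadata$trial_id[0],
    onset_ms = as.numeric(unlist(acc$onset_ms)),
    direction = as.numeric(unlist(acc$direction)),
    angle = as.numeric(unlist(acc$angle)),
    magnitude_deg = as.numeric(unlist(acc$magnitude_deg)),
    peak_velocity = as.numeric(unlist(acc$peak_velocity)),
    status = as.character(unlist(acc$status))
  )
}

#' @rdname detect_saccades
#' @param events an event table from `detect_saccades()`.
#' @export
saccade_events <- function(events) filter(events, .data$status == "ok")

#' Detection across a range of velocity thresholds
#'
#' Re-runs [detect_saccades()] with each threshold multiplier in
#' `k_values`, optionally applying a `downstream` summary function to each
#' event set. On noise-free data the event set at a larger `k` is a subset
#' of the event set at a smaller `k`.
#'
#' @param ge a [gaze_epochs] object.
#' @param k_values threshold multipliers (default `c(2, 3, 4, 5)`).
#' @param params base [detect_params]; `k_threshold` is overridden.
#' @param downstream optional function applied to each event table.
#' @return tibble with one row per `k`: `k`, `n_events`, list-columns
#'   `events` and (when supplied) `downstream`.
#' @export
threshold_sweep <- function(ge, k_values = c(2, 3, 4, 5),
                            params = detect_params(), downstream = NULL) {
  res <- purrr::map(k_values, function(k) {
    p <- params; p$k_threshold <- k
    detect_saccades(ge, p)
  })
  out <- tibble(
    k = k_values,
    n_events = vapply(res, function(e) nrow(saccade_events(e)), integer(1)),
    events = res
  )
  if (!is.null(downstream))
    out$downstream <- purrr::map(res, downstream)
  out
}
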