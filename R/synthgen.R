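#' Configuration for the synthetic gaze + EEG experiment
#'
#' Defines a complete simulated spatial-attention experiment: two tasks
#' (perceptual and working-memory selection) with lateral objects at fixed
#' eccentricity, per-trial gaze traces (fixational drift, blinks, planted
#' microsaccades with a direction bias emerging in the post-cue attention
#' window) and epoched EEG (cue-locked lateralized N2pc, saccade-locked
#' EOG deflection and occipital lambda response, post-cue alpha-band
#' lateralization, 1/f-plus-white background noise), plus lognormal
#' response times and Bernoulli accuracy. Every random draw descends from
#' `seed` through per-trial substreams, so any trial regenerates
#' identically regardless of order.
#'
#' Class probabilities give the planted trial mix: a `"toward"`/`"away"`
#' trial carries one microsaccade with onset inside `saccade_bias_window`
#' directed toward/away from the cued side; a `"none"` trial carries no
#' saccade onset inside that window. Background microsaccades at
#' `bg_rate_hz` occur outside the window identically for all classes.
#' `n2pc_amp_by_class` is the planted mean of the contralateral-minus-
#' ipsilateral wave over `n2pc_window`, in microvolt (the Gaussian bump is
#' scaled so its window average equals this value); `n2pc_amp_sd` adds
#' between-participant variability around it. `alpha_lat_amp` is the
#' asymmetry depth d of the 10-Hz amplitude: contra `(1 - d)`, ipsi
#' `(1 + d)` times `alpha_amp`.
#'
#' @param n_participants,trials_per_task experiment size (defaults 23 and
#'   600, i.e. 1200 trials per participant over both tasks).
#' @param gaze_rate,eeg_rate sampling rates in Hz (1000 / 1024).
#' @param epoch_window epoch in ms relative to cue, half-open
#'   (`c(-1000, 1500)`).
#' @param object_eccentricity object eccentricity in degrees (5).
#' @param saccade_bias_window attention window for planted saccades, ms
#'   (`c(150, 400)`).
#' @param p_toward,p_away,p_none trial-class probabilities (must sum to 1).
#' @param sacc_mag_range planted saccade magnitudes, degrees (uniform on
#'   `c(0.1, 1)`).
#' @param sacc_duration_ms raised-cosine saccade displacement duration (20).
#' @param bg_rate_hz rate of background saccades outside the bias window.
#' @param n2pc_amp_by_class named planted window-mean difference-wave
#'   amplitude per class, microvolt.
#' @param n2pc_amp_sd between-participant SD of class amplitudes, microvolt.
#' @param n2pc_window,n2pc_sd_ms N2pc window (ms) and bump SD (ms).
#' @param lambda_delay_ms,lambda_amp,lambda_sd_ms occipital lambda response:
#'   delay after saccade onset, amplitude (microvolt), bump SD.
#' @param eog_gain horizontal EOG step gain, microvolt per degree.
#' @param alpha_freq,alpha_amp,alpha_lat_amp,alpha_onset_ms alpha
#'   oscillation frequency (Hz), base amplitude (microvolt), asymmetry
#'   depth, and lateralization onset (ms).
#' @param noise_sd total EEG noise SD per channel, microvolt (white and
#'   1/f-shaped noise in equal variance shares).
#' @param drift_sd slow fixational drift: SD of the accumulated positional
#'   excursion over the epoch, degrees.
#' @param gaze_noise_sd white gaze measurement noise SD, degrees.
#' @param blink_prob per-trial blink probability (zero-run insertion).
#' @param rt_mean_ms,rt_sdlog,p_correct behavioral generators per class.
#' @param channels EEG montage; must include PO7, PO8, Oz, HEOG.
#' @param seed integer master seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_participants = 23,
                       trials_per_task = 600,
                       gaze_rate = 1000,
                       eeg_rate = 1024,
                       epoch_window = c(-1000, 1500),
                       object_eccentricity = 5,
                       saccade_bias_window = c(150, 400),
                       p_toward = 0.36, p_away = 0.24, p_none = 0.40,
                       sacc_mag_range = c(0.1, 1.0),
                       sacc_duration_ms = 20,
                       bg_rate_hz = 0.5,
                       n2pc_amp_by_class = c(toward = -1.5, none = -0.5,
                                             away = 0),
                       n2pc_amp_sd = 0.6,
                       n2pc_window = c(200, 300),
                       n2pc_sd_ms = 15,
                       lambda_delay_ms = 125,
                       lambda_amp = 3,
                       lambda_sd_ms = 15,
                       eog_gain = 16,
                       alpha_freq = 10,
                       alpha_amp = 2,
                       alpha_lat_amp = 0.15,
                       alpha_onset_ms = 400,
                       noise_sd = 5,
                       drift_sd = 0.1,
                       gaze_noise_sd = 0.002,
                       blink_prob = 0.05,
                       rt_mean_ms = c(toward = 700, none = 720, away = 740),
                       rt_sdlog = 0.25,
                       p_correct = c(toward = 0.92, none = 0.90,
                                     away = 0.89),
                       channels = c("PO7", "PO8", "Oz", "HEOG"),
                       seed = 1) {
  cfg <- as.list(environment())
  probs <- c(p_toward, p_away, p_none)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop("class probabilities must be non-negative and sum to 1",
         call. = FALSE)
  if (gaze_rate <= 0 || eeg_rate <= 0)
    stop("sampling rates must be positive", call. = FALSE)
  stop_if_not_window(saccade_bias_window, epoch_window, "bias window")
  stop_if_not_window(n2pc_window, epoch_window, "N2pc window")
  need <- c("PO7", "PO8", "Oz", "HEOG")
  if (!all(need %in% channels))
    stop("channels must include ", paste(need, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(c("toward", "none", "away"), names(n2pc_amp_by_class))
  if (length(miss))
    stop("n2pc_amp_by_class must name classes toward/none/away",
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

# time axes
gaze_time_axis <- function(config) {
  step <- 1000 / config$gaze_rate
  n <- round(diff(config$epoch_window) / step)
  config$epoch_window[1] + (seq_len(n) - 1) * step
}
eeg_time_axis <- function(config) {
  step <- 1000 / config$eeg_rate
  n <- round(diff(config$epoch_window) / step)
  config$epoch_window[1] + (seq_len(n) - 1) * step
}


#' Simulate one gaze trial
#'
#' Generates a single cue-locked gaze trace: smoothed random-walk drift on
#' both axes, white measurement noise, step-like saccade displacements with
#' a raised-cosine profile (horizontal axis only, matching the lateral task
#' geometry), and an optional blink inserted as a zero run. A
#' `"toward"`/`"away"` trial plants one saccade with onset inside the bias
#' window directed at/away from the cued side; background saccades with
#' random direction occur outside the window for all classes alike, so no
#' saccade onset falls inside the bias window on a `"none"` trial.
#'
#' @param class_label `"toward"`, `"away"`, or `"none"`.
#' @param cued_side `"left"` or `"right"`.
#' @param config a [sim_config].
#' @param seed integer substream seed.
#' @return list: `x`, `y` (degrees), `time_ms`, and `saccades` (tibble of
#'   planted events: `onset_ms`, `direction`, `magnitude_deg`,
#'   `in_window`).
#' @export
simulate_gaze_trial <- function(class_label, cued_side, config, seed = NULL) {
  stopifnot(class_label %in% c("toward", "away", "none"),
            cued_side %in% c("left", "right"))
  time <- gaze_time_axis(config)
  n <- length(time)
  win <- config$saccade_bias_window
  with_seed(seed, {
    # planted in-window saccade for toward/away
    onsets <- numeric(0); dirs <- numeric(0); mags <- numeric(0)
    inw <- logical(0)
    if (class_label != "none") {
      cued_sign <- if (cued_side == "left") -1 else 1
      onsets <- floor(runif(1, win[1] + 5, win[2] - 10))
      dirs <- if (class_label == "toward") cued_sign else -cued_sign
      mags <- runif(1, config$sacc_mag_range[1], config$sacc_mag_range[2])
      inw <- TRUE
    }
    # background saccades, identical generation for every class, kept clear
    # of the bias window (and of its characterization margins)
    dur_s <- diff(config$epoch_window) / 1000
    n_bg <- stats::rpois(1, config$bg_rate_hz * dur_s)
    if (n_bg > 0) {
      lo <- config$epoch_window[1] + 150
      hi <- config$epoch_window[2] - 150
      cand <- floor(runif(n_bg, lo, hi))
      cand <- cand[cand < win[1] - 150 | cand > win[2] + 120]
      cand <- sort(cand)
      keep <- logical(length(cand))
      last <- -Inf
      for (i in seq_along(cand)) {
        if (cand[i] - last >= 120) { keep[i] <- TRUE; last <- cand[i] }
      }
      cand <- cand[keep]
      if (length(cand)) {
        onsets <- c(onsets, cand)
        dirs <- c(dirs, sample(c(-1, 1), length(cand), replace = TRUE))
        mags <- c(mags, runif(length(cand), config$sacc_mag_range[1],
                              config$sacc_mag_range[2]))
        inw <- c(inw, rep(FALSE, length(cand)))
      }
    }
    ord <- order(onsets)
    sacc <- tibble::new_tibble(
      list(onset_ms = onsets[ord], direction = dirs[ord],
           magnitude_deg = mags[ord], in_window = inw[ord]),
      nrow = length(ord))
    drift <- function() {
      # slow drift: random walk on a 20-ms knot grid, spline-interpolated,
      # calibrated so the end-of-epoch excursion SD is drift_sd
      if (config$drift_sd <= 0) return(rep(0, n))
      knot_step <- max(2L, round(0.02 * config$gaze_rate))
      knots <- seq(1L, n + knot_step, by = knot_step)
      w <- cumsum(rnorm(length(knots),
                        0, config$drift_sd / sqrt(length(knots))))
      stats::spline(knots, w, xout = seq_len(n))$y
    }
    x <- drift()
    y <- drift()
    if (config$gaze_noise_sd > 0) {
      x <- x + rnorm(n, 0, config$gaze_noise_sd)
      y <- y + rnorm(n, 0, config$gaze_noise_sd)
    }
    for (i in seq_len(nrow(sacc))) {
      x <- add_step(x, time, sacc$onset_ms[i], config$sacc_duration_ms,
                    sacc$direction[i] * sacc$magnitude_deg[i])
    }
    if (config$blink_prob > 0 && runif(1) < config$blink_prob) {
      bdur <- runif(1, 100, 300)
      bstart <- runif(1, config$epoch_window[1],
                      config$epoch_window[2] - bdur)
      bi <- which(time >= bstart & time < bstart + bdur)
      x[bi] <- 0
      y[bi] <- 0
    }
    list(x = x, y = y, time_ms = time, saccades = sacc)
  })
}

#' Simulate one EEG trial
#'
#' Builds a cue-locked epoch over the configured montage containing: a
#' Gaussian N2pc bump (scaled so its mean over the N2pc window equals
#' `n2pc_amp`) on the channel contralateral to the cued side; a
#' saccade-locked EOG step on HEOG whose sign and size follow each
#' saccade; a lambda bump on Oz at `lambda_delay_ms` after each saccade
#' onset; a 10-Hz oscillation on PO7/PO8 with random phase and a
#' contra-smaller-than-ipsi amplitude asymmetry from `alpha_onset_ms`; and
#' per-channel background noise (equal-variance white plus 1/f).
#'
#' @inheritParams simulate_gaze_trial
#' @param saccades planted saccade tibble from [simulate_gaze_trial()].
#' @param n2pc_amp planted window-mean difference amplitude for this trial
#'   (microvolt); defaults to the class value in `config`.
#' @return channels x time matrix (microvolt).
#' @export
simulate_eeg_trial <- function(class_label, cued_side, saccades, config,
                               seed = NULL,
                               n2pc_amp = config$n2pc_amp_by_class[[class_label]],
                               consts = eeg_trial_consts(config)) {
  time <- consts$time
  n <- length(time)
  chs <- config$channels
  contra_ch <- if (cued_side == "left") match("PO8", chs) else match("PO7", chs)
  ipsi_ch <- if (cued_side == "left") match("PO7", chs) else match("PO8", chs)
  with_seed(seed, {
    m <- matrix(0, length(chs), n, dimnames = list(chs, NULL))
    # background noise: equal-variance white + 1/f shares
    if (config$noise_sd > 0) {
      s <- config$noise_sd / sqrt(2)
      for (ci in seq_along(chs))
        m[ci, ] <- rnorm(n, 0, s) +
          s * pink_from_scale(n, consts$pink_scale)
    }
    # cue-locked N2pc bump on the contralateral channel, scaled so its
    # mean over the N2pc window equals n2pc_amp
    if (n2pc_amp != 0)
      m[contra_ch, ] <- m[contra_ch, ] + consts$unit_bump * n2pc_amp
    # alpha oscillation with planted lateralization from alpha_onset_ms
    if (config$alpha_amp > 0) {
      phi <- runif(1, 0, 2 * pi)
      base <- config$alpha_amp *
        sin(consts$alpha_phase + phi) * consts$alpha_env
      d <- config$alpha_lat_amp
      m[contra_ch, ] <- m[contra_ch, ] + (1 - d) * base
      m[ipsi_ch, ] <- m[ipsi_ch, ] + (1 + d) * base
    }
    # saccade-locked components
    hch <- match("HEOG", chs); och <- match("Oz", chs)
    for (i in seq_len(nrow(saccades))) {
      on <- saccades$onset_ms[i]
      step <- saccades$direction[i] * saccades$magnitude_deg[i]
      m[hch, ] <- add_step(m[hch, ], time, on, config$sacc_duration_ms,
                           config$eog_gain * step)
      m[och, ] <- add_bump(m[och, ], time, on + config$lambda_delay_ms,
                           config$lambda_sd_ms, config$lambda_amp)
    }
    m
  })
}

# per-configuration constants reused across trials
eeg_trial_consts <- function(config) {
  time <- eeg_time_axis(config)
  n <- length(time)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)
  pink_scale <- ifelse(f > 0, 1 / sqrt(f), 0)
  center <- mean(config$n2pc_window)
  bump <- exp(-(time - center)^2 / (2 * config$n2pc_sd_ms^2))
  widx <- window_idx(time, config$n2pc_window)
  list(time = time,
       pink_scale = pink_scale,
       unit_bump = bump / mean(bump[widx]),
       alpha_phase = 2 * pi * config$alpha_freq * time / 1000,
       alpha_env = pmin(pmax((time - config$alpha_onset_ms) / 100, 0), 1))
}

pink_from_scale <- function(n, scale) {
  y <- Re(fft(fft(rnorm(n)) * scale, inverse = TRUE)) / n
  y / sd(y)
}

# in-place-style helpers restricted to the affected sample range
add_step <- function(x, time, onset_ms, duration_ms, amp) {
  step <- time[2] - time[1]
  n <- length(x)
  i0 <- max(1L, ceiling((onset_ms - time[1]) / step) + 1L)
  i1 <- min(n, floor((onset_ms + duration_ms - time[1]) / step) + 1L)
  if (i0 <= i1) {
    u <- (time[i0:i1] - onset_ms) / duration_ms
    x[i0:i1] <- x[i0:i1] + amp * (1 - cos(pi * pmin(pmax(u, 0), 1))) / 2
  }
  if (i1 < n) x[(i1 + 1):n] <- x[(i1 + 1):n] + amp
  x
}

add_bump <- function(x, time, center_ms, sd_ms, amp) {
  step <- time[2] - time[1]
  n <- length(x)
  i0 <- max(1L, floor((center_ms - 5 * sd_ms - time[1]) / step))
  i1 <- min(n, ceiling((center_ms + 5 * sd_ms - time[1]) / step))
  if (i0 <= i1)
    x[i0:i1] <- x[i0:i1] +
      amp * exp(-(time[i0:i1] - center_ms)^2 / (2 * sd_ms^2))
  x
}

#' Simulate one participant
#'
#' Generates both tasks for one participant: exactly balanced cued sides
#' within each task (difference at most 1), class labels drawn from the
#' configured probabilities, per-trial gaze and EEG from their own seeded
#' substreams, and behavioral responses (lognormal RT with the configured
#' per-class mean, Bernoulli accuracy).
#'
#' @param config a [sim_config].
#' @param participant integer participant id.
#' @return list: `gaze` ([gaze_epochs]), `eeg` ([eeg_epochs]), `metadata`
#'   tibble (with the planted `class_true`), `truth` (planted saccades and
#'   per-participant planted class amplitudes).
#' @export
simulate_participant <- function(config, participant) {
  seed <- config$seed
  classes <- c("toward", "away", "none")
  amp_offsets <- with_seed(derive_seed(seed, participant, 9001),
                           stats::setNames(rnorm(3, 0, config$n2pc_amp_sd),
                                           classes))
  tasks <- c("perception", "wm")
  npt <- config$trials_per_task
  gtime <- gaze_time_axis(config)
  etime <- eeg_time_axis(config)
  ntot <- npt * length(tasks)
  # transposed stores so each trial writes a contiguous block
  gxT <- matrix(NA_real_, length(gtime), ntot)
  gyT <- matrix(NA_real_, length(gtime), ntot)
  eeT <- array(NA_real_, c(length(config$channels), length(etime), ntot))
  task_v <- rep(tasks, each = npt)
  side_v <- character(ntot); class_v <- character(ntot)
  rt_v <- numeric(ntot); corr_v <- logical(ntot)
  ts_trial <- list(); ts_sacc <- list()
  consts <- eeg_trial_consts(config)
  for (ti in seq_along(tasks)) {
    sides <- rep(c("left", "right"), length.out = npt)
    sides <- with_seed(derive_seed(seed, participant, ti, 1), sample(sides))
    cls <- with_seed(derive_seed(seed, participant, ti, 2),
                     sample(classes, npt, replace = TRUE,
                            prob = c(config$p_toward, config$p_away,
                                     config$p_none)))
    for (j in seq_len(npt)) {
      tid <- (ti - 1L) * npt + j
      g <- simulate_gaze_trial(cls[j], sides[j], config,
                               seed = derive_seed(seed, participant, tid, 3))
      amp <- config$n2pc_amp_by_class[[cls[j]]] + amp_offsets[[cls[j]]]
      e <- simulate_eeg_trial(cls[j], sides[j], g$saccades, config,
                              seed = derive_seed(seed, participant, tid, 4),
                              n2pc_amp = amp, consts = consts)
      gxT[, tid] <- g$x
      gyT[, tid] <- g$y
      eeT[, , tid] <- e
      beh <- with_seed(derive_seed(seed, participant, tid, 5), {
        mu <- config$rt_mean_ms[[cls[j]]]
        list(rt = rlnorm(1, log(mu) - config$rt_sdlog^2 / 2,
                         config$rt_sdlog),
             correct = rbinom(1, 1, config$p_correct[[cls[j]]]) == 1)
      })
      side_v[tid] <- sides[j]; class_v[tid] <- cls[j]
      rt_v[tid] <- beh$rt; corr_v[tid] <- beh$correct
      if (nrow(g$saccades)) {
        k <- length(ts_trial) + 1L
        ts_trial[[k]] <- rep(tid, nrow(g$saccades))
        ts_sacc[[k]] <- g$saccades
      }
    }
  }
  gx <- t(gxT); gy <- t(gyT)
  ee <- aperm(eeT, c(3, 1, 2))
  rm(gxT, gyT, eeT)
  metadata <- tibble(participant = participant, trial_id = seq_len(ntot),
                     task = task_v, cued_side = side_v, class_true = class_v,
                     rt_ms = rt_v, correct = corr_v)
  sacc_all <- if (length(ts_sacc)) bind_rows(ts_sacc) else
    tibble(onset_ms = numeric(), direction = numeric(),
           magnitude_deg = numeric(), in_window = logical())
  tid_all <- if (length(ts_trial)) unlist(ts_trial) else integer(0)
  truth <- list(
    saccades = dplyr::bind_cols(
      tibble(participant = rep(participant, length(tid_all)),
             trial_id = tid_all,
             task = task_v[tid_all] %||% character(0)),
      sacc_all),
    participant_amps = tibble(
      participant = participant, class = classes,
      amp = as.numeric(config$n2pc_amp_by_class[classes]) +
        as.numeric(amp_offsets[classes]))
  )
  list(gaze = gaze_epochs(gx, gy, gtime, metadata),
       eeg = eeg_epochs(ee, config$channels, config$eeg_rate, etime,
                        metadata),
       metadata = metadata, truth = truth)
}

#' Generate (and optionally write) a full synthetic experiment
#'
#' Runs [simulate_participant()] for every participant. With `dir` set,
#' each participant's gaze table (CSV) and EEG epochs (raw float64 array
#' with JSON sidecar) are written to disk together with the pooled trial
#' metadata (CSV) and the ground truth (JSON: planted saccades, class
#' labels, planted amplitudes, behavioral means, full configuration);
#' in-memory data are then discarded participant by participant, keeping
#' the footprint flat. Without `dir` the per-participant objects are
#' returned (sized for reduced configurations; the default experiment is
#' large).
#'
#' @param config a [sim_config].
#' @param dir optional output directory (created if needed).
#' @return with `dir`: invisibly, a list with `dir`, pooled `metadata` and
#'   `truth`; without: a list with `participants` (list of
#'   [simulate_participant()] results), pooled `metadata` and `truth`.
#' @export
simulate_experiment <- function(config, dir = NULL) {
  mds <- list(); saccs <- list(); amps <- list(); parts <- list()
  for (p in seq_len(config$n_participants)) {
    sim <- simulate_participant(config, p)
    mds[[p]] <- sim$metadata
    saccs[[p]] <- sim$truth$saccades
    amps[[p]] <- sim$truth$participant_amps
    if (is.null(dir)) {
      parts[[p]] <- sim
    } else {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_gaze_table(sim$gaze, file.path(dir, sprintf("gaze_p%02d.csv", p)))
      write_eeg_epochs(sim$eeg, file.path(dir, sprintf("eeg_p%02d", p)))
    }
  }
  metadata <- bind_rows(mds)
  truth <- list(saccades = bind_rows(saccs),
                participant_amps = bind_rows(amps),
                class_labels = metadata[, c("participant", "trial_id",
                                            "task", "class_true")],
                behavioral_means = list(rt_mean_ms = config$rt_mean_ms,
                                        p_correct = config$p_correct))
  if (!is.null(dir)) {
    readr::write_csv(metadata, file.path(dir, "metadata.csv"),
                     progress = FALSE)
    jsonlite::write_json(
      c(truth, list(config = unclass(config))),
      file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE,
      dataframe = "columns")
    return(invisible(list(dir = dir, metadata = metadata, truth = truth)))
  }
  list(participants = parts, metadata = metadata, truth = truth)
}
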