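#' Label saccade direction relative to the cued side
#'
#' Maps each event's left/right direction sign onto task semantics: a shift
#' in the direction of the cued object's (memorized) location is `"toward"`,
#' the opposite is `"away"`. Leftward is direction -1, so a leftward shift
#' on a left-cued trial is toward.
#'
#' @param events event tibble from [detect_saccades()].
#' @param metadata tibble with `trial_id` and `cued_side`
#'   (`"left"`/`"right"`).
#' @return the event tibble with an added `label` column.
#' @export
label_direction <- function(events, metadata) {
  stopifnot(all(c("trial_id", "cued_side") %in% names(metadata)))
  ev <- left_join(events, metadata[, c("trial_id", "cued_side")],
                  by = "trial_id")
  if (any(!ev$cued_side %in% c("left", "right")))
    stop("cued_side must be 'left' or 'right' for every trial", call. = FALSE)
  cued_sign <- ifelse(ev$cued_side == "left", -1, 1)
  ev$label <- ifelse(ev$direction == cued_sign, "toward", "away")
  ev$cued_side <- NULL
  ev
}

#' Saccade-rate time courses and toward-away bias
#'
#' Rates (Hz) from event onsets pooled over trials, computed in a sliding
#' window of `window_ms` centered on each time step: the rate at time `t`
#' is the count of onsets in `[t - w/2, t + w/2)` divided by
#' `n_trials x` the realized window length in seconds. Windows truncated at
#' the epoch edges are normalized by their realized length. Separate curves
#' are returned for toward- and away-labelled events together with their
#' difference (the directional bias).
#'
#' @param events labelled event tibble (see [label_direction()]); only
#'   `status == "ok"` rows are counted.
#' @param n_trials number of trials the events were pooled over.
#' @param time_range length-2 vector, ms; the epoch window.
#' @param window_ms sliding window width (default 50).
#' @param step_ms step between window centers (default 1).
#' @return tibble with `time_ms`, `rate_toward`, `rate_away`, `bias` (Hz).
#' @export
saccade_rate <- function(events, n_trials, time_range = c(-1000, 1500),
                         window_ms = 50, step_ms = 1) {
  if (n_trials <= 0) stop("n_trials must be positive", call. = FALSE)
  ev <- saccade_events(events)
  centers <- seq(time_range[1], time_range[2], by = step_ms)
  half <- window_ms / 2
  lo <- pmax(centers - half, time_range[1])
  hi <- pmin(centers + half, time_range[2])
  win_s <- (hi - lo) / 1000
  count_curve <- function(onsets) {
    # onsets in [lo, hi) per center, via cumulative counts on sorted onsets
    s <- sort(onsets)
    (findInterval(hi, s, left.open = TRUE) -
       findInterval(lo, s, left.open = TRUE))
  }
  n_tow <- count_curve(ev$onset_ms[ev$label == "toward"])
  n_away <- count_curve(ev$onset_ms[ev$label == "away"])
  tibble(
    time_ms = centers,
    rate_toward = n_tow / (n_trials * win_s),
    rate_away = n_away / (n_trials * win_s),
    bias = (n_tow - n_away) / (n_trials * win_s)
  )
}

#' Time-by-size decomposition of the saccade-rate bias
#'
#' Splits the toward-minus-away rate into overlapping saccade-size bins of
#' `size_bin_deg` degrees advanced in increments of `size_step_deg`
#' (half-open `[s, s + bin)`), revealing which saccade sizes carry the
#' directional bias.
#'
#' @inheritParams saccade_rate
#' @param size_bin_deg size-bin width in degrees (default 0.2).
#' @param size_step_deg increment between bin lower edges (default 0.04).
#' @param size_range range of bin lower edges; defaults to covering the
#'   observed magnitudes.
#' @return long tibble: `size_deg` (bin lower edge), `time_ms`, `bias` (Hz).
#' @export
rate_by_size <- function(events, n_trials, time_range = c(-1000, 1500),
                         window_ms = 50, step_ms = 1,
                         size_bin_deg = 0.2, size_step_deg = 0.04,
                         size_range = NULL) {
  ev <- saccade_events(events)
  if (is.null(size_range)) {
    if (nrow(ev) == 0) size_range <- c(0, size_bin_deg)
    else size_range <- c(0, max(ev$magnitude_deg))
  }
  lowers <- seq(size_range[1], max(size_range[2] - size_step_deg, size_range[1]),
                by = size_step_deg)
  purrr::map_dfr(lowers, function(lo) {
    sub <- filter(ev, .data$magnitude_deg >= lo,
                  .data$magnitude_deg < lo + size_bin_deg)
    rc <- saccade_rate(sub, n_trials, time_range, window_ms, step_ms)
    tibble(size_deg = lo, time_ms = rc$time_ms, bias = rc$bias)
  })
}
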