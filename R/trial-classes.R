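#' Classify trials by the first gaze shift in the attention window
#'
#' Sorts trials into `"toward"`, `"away"`, and `"none"` classes based on
#' detected gaze shifts in the post-cue attention window (default
#' `[150, 400)` ms, half-open). Exclusions are applied first: a trial with
#' any missing gaze sample inside the window is excluded with reason
#' `"missing-data"`; a trial with any sub-minimum shift (magnitude below
#' the detection minimum) inside the window is excluded with reason
#' `"sub-minimum-shift"`. Otherwise the direction of the *first* detected
#' in-window shift relative to the cued side decides toward/away, and a
#' trial with no in-window shift is `"none"`.
#'
#' @param events event tibble from [detect_saccades()] (all statuses).
#' @param ge the blink-masked [gaze_epochs] the events came from.
#' @param window classification window in ms, half-open (default
#'   `c(150, 400)`).
#' @return tibble with `trial_id`, `cued_side`, `class`
#'   (`toward`/`away`/`none`/`excluded`), `exclusion_reason`
#'   (`missing-data`/`sub-minimum-shift`/`n/a`), `first_saccade_onset_ms`,
#'   plus any further metadata columns (`task`, `participant`, ...).
#' @export
classify_trials <- function(events, ge, window = c(150, 400)) {
  md <- ge$metadata
  if (!"cued_side" %in% names(md) || any(!md$cued_side %in% c("left", "right")))
    stop("gaze metadata must carry cued_side ('left'/'right')", call. = FALSE)
  stop_if_not_window(window, range(ge$time_ms) + c(0, 1), "class window")
  widx <- window_idx(ge$time_ms, window)
  in_win <- events$onset_ms >= window[1] & events$onset_ms < window[2]

  out <- md
  out$class <- NA_character_
  out$exclusion_reason <- "n/a"
  out$first_saccade_onset_ms <- NA_real_
  for (i in seq_len(nrow(md))) {
    tid <- md$trial_id[i]
    if (anyNA(ge$x[i, widx])) {
      out$class[i] <- "excluded"
      out$exclusion_reason[i] <- "missing-data"
      next
    }
    ev <- events[events$trial_id == tid & in_win, , drop = FALSE]
    if (any(ev$status == "sub_minimum")) {
      out$class[i] <- "excluded"
      out$exclusion_reason[i] <- "sub-minimum-shift"
      next
    }
    ev <- ev[ev$status == "ok", , drop = FALSE]
    if (nrow(ev) == 0) {
      out$class[i] <- "none"
      next
    }
    first <- ev[which.min(ev$onset_ms), ]
    cued_sign <- if (md$cued_side[i] == "left") -1 else 1
    out$class[i] <- if (first$direction == cued_sign) "toward" else "away"
    out$first_saccade_onset_ms[i] <- first$onset_ms
  }
  dplyr::relocate(out, "trial_id", "cued_side", "class", "exclusion_reason",
                  "first_saccade_onset_ms")
}

#' Per-participant trial-class proportions
#'
#' Proportions of toward/away/none trials over the non-excluded trials,
#' per participant (or another grouping column), plus a mean and standard
#' error across participants. Participants with zero usable trials are
#' flagged with `NA` proportions rather than dropped silently.
#'
#' @param class_table output of [classify_trials()].
#' @param by grouping column name (default `"participant"`; falls back to a
#'   single group when absent).
#' @return list with `by_participant` (tibble of proportions) and `summary`
#'   (tibble of mean and SE per class across participants).
#' @export
class_proportions <- function(class_table, by = "participant") {
  tbl <- class_table
  if (!by %in% names(tbl)) tbl[[by]] <- 1L
  classes <- c("toward", "away", "none")
  byp <- tbl |>
    group_by(.data[[by]]) |>
    summarise(
      n_usable = sum(.data$class %in% classes),
      p_toward = ifelse(n_usable > 0,
                        sum(.data$class == "toward") / n_usable, NA_real_),
      p_away = ifelse(n_usable > 0,
                      sum(.data$class == "away") / n_usable, NA_real_),
      p_none = ifelse(n_usable > 0,
                      sum(.data$class == "none") / n_usable, NA_real_),
      .groups = "drop"
    )
  longp <- tidyr::pivot_longer(byp, dplyr::all_of(paste0("p_", classes)),
                               names_to = "class", names_prefix = "p_",
                               values_to = "p")
  summ <- longp |>
    group_by(.data$class) |>
    summarise(mean = mean(.data$p, na.rm = TRUE),
              se = sd(.data$p, na.rm = TRUE) /
                sqrt(sum(!is.na(.data$p))),
              .groups = "drop")
  list(by_participant = byp, summary = summ)
}
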