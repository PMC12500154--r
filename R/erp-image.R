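#' Latency-sorted single-trial ERP image
#'
#' Sorts single-trial voltage series by a per-trial reference event latency
#' (here: the first toward-microsaccade onset) and smooths the resulting
#' trials x time matrix first across sorted neighbouring trials (Gaussian
#' kernel spanning `trial_smooth_frac` of the rows) and then across time
#' (Gaussian kernel spanning `time_smooth_ms`). A component locked to the
#' reference event shows as a ridge tracking the sorted onset curve; a
#' cue-locked component stays a vertical band. The stated kernel spans are
#' interpreted as the full kernel width, with SD = span / 4; sorting is
#' stable, so tied onsets keep their input order.
#'
#' @param series trials x time matrix of single-trial voltages (one row per
#'   included trial; for the lateralized derivation use [trialwise_diff()]).
#' @param onsets per-trial reference onset in ms (same order as rows).
#' @param time_ms time axis of the columns.
#' @param trial_smooth_frac fraction of rows spanned by the trial-dimension
#'   kernel (default 0.10); 0 disables trial smoothing.
#' @param time_smooth_ms span of the time-dimension kernel in ms
#'   (default 50); 0 disables time smoothing.
#' @param label derivation label carried through to plots.
#' @return an `erp_image` object: smoothed sorted `matrix`, sorted
#'   `onsets`, `time_ms`, the smoothing parameters, `label`.
#' @export
build_erp_image <- function(series, onsets, time_ms,
                            trial_smooth_frac = 0.10, time_smooth_ms = 50,
                            label = "") {
  series <- as.matrix(series)
  stopifnot(nrow(series) == length(onsets),
            ncol(series) == length(time_ms))
  if (nrow(series) < 10)
    stop("need at least 10 trials to build an ERP image", call. = FALSE)
  ord <- order(onsets)  # stable: ties keep input order
  m <- series[ord, , drop = FALSE]
  if (trial_smooth_frac > 0) {
    sd_tr <- trial_smooth_frac * nrow(m) / 4
    if (sd_tr > 0)
      m <- apply(m, 2L, smooth_gaussian, sd = sd_tr, pad = "renorm")
  }
  if (time_smooth_ms > 0) {
    rate <- 1000 / diff(time_ms[1:2])
    sd_t <- time_smooth_ms * rate / 1000 / 4
    m <- smooth_rows(m, sd = sd_t, pad = "renorm")
  }
  structure(list(matrix = m, onsets = onsets[ord], time_ms = time_ms,
                 trial_smooth_frac = trial_smooth_frac,
                 time_smooth_ms = time_smooth_ms, label = label),
            class = "erp_image")
}

#' @export
print.erp_image <- function(x, ...) {
  cat("<erp_image> ", nrow(x$matrix), " sorted trials x ",
      ncol(x$matrix), " samples", if (nzchar(x$label)) paste0(" [", x$label, "]"),
      "\n", sep = "")
  invisible(x)
}

#' Temporal-alignment statistic for an ERP image
#'
#' Quantifies whether the imaged component is locked to the sorting event:
#' for each row, the latency of the component extremum is located inside a
#' search window, and the Spearman rank correlation between those latencies
#' and the sorted reference onsets is computed with a bootstrap confidence
#' interval (resampling rows). A correlation near 1 indicates a component
#' locked to the reference event; near 0, a component locked to the cue.
#' Extremum methods: `"abs"` (largest absolute value), `"min"`/`"max"`
#' (signed extremum, e.g. `"min"` for a negative-going component), and
#' `"slope"` (largest absolute time derivative, appropriate for step-like
#' signals such as the horizontal EOG whose plateau has no peak). Rows that
#' are flat inside the window are skipped and counted.
#'
#' @param img an `erp_image`.
#' @param search_window latency search window in ms (default `c(150, 500)`).
#' @param method extremum definition (see Details).
#' @param n_boot bootstrap resamples for the CI (default 1000).
#' @param seed optional seed for the bootstrap.
#' @return one-row tibble: `rho`, `ci_low`, `ci_high`, `n_rows`,
#'   `n_skipped`, `method`.
#' @export
alignment_statistic <- function(img, search_window = c(150, 500),
                                method = c("abs", "min", "max", "slope"),
                                n_boot = 1000, seed = NULL) {
  method <- match.arg(method)
  idx <- which(img$time_ms >= search_window[1] &
                 img$time_ms <= search_window[2])
  if (length(idx) < 3) stop("search window too narrow", call. = FALSE)
  tm <- img$time_ms[idx]
  lat <- apply(img$matrix[, idx, drop = FALSE], 1L, function(row) {
    if (all(is.na(row)) || diff(range(row, na.rm = TRUE)) == 0)
      return(NA_real_)
    k <- switch(method,
                abs = which.max(abs(row)),
                min = which.min(row),
                max = which.max(row),
                slope = which.max(abs(diff(row))) + 1L)
    tm[k]
  })
  keep <- !is.na(lat)
  n_skipped <- sum(!keep)
  lat <- lat[keep]
  ons <- img$onsets[keep]
  rho <- cor(lat, ons, method = "spearman")
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    i <- sample.int(length(lat), replace = TRUE)
    suppressWarnings(cor(lat[i], ons[i], method = "spearman"))
  }, numeric(1)))
  ci <- quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  tibble(rho = rho, ci_low = ci[1], ci_high = ci[2],
         n_rows = length(lat), n_skipped = n_skipped, method = method)
}
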