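# Independent rule-replay oracles used across the suite. These are written
# as literal, sample-by-sample implementations of the stated rules, kept
# deliberately separate from the package's vectorized code paths.

# Brute-force microsaccade detector: scan every sample, apply the rules
# literally (1D horizontal mode).
naive_detect <- function(x, time, params = detect_params(), rate = 1000) {
  n <- length(x)
  v <- rep(NA_real_, n)
  for (i in 2:n) v[i] <- abs(x[i] - x[i - 1]) * rate
  w <- max(3, round(params$smooth_window_ms * rate / 1000))
  if (w %% 2 == 0) w <- w + 1
  r <- (w - 1) / 2
  sdk <- (w - 1) / 5
  wts <- exp(-((-r):r)^2 / (2 * sdk^2))
  vs <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(v[i])) next
    num <- 0; den <- 0
    for (k in (-r):r) {
      j <- i + k
      if (j >= 1 && j <= n && !is.na(v[j])) {
        num <- num + wts[k + r + 1] * v[j]
        den <- den + wts[k + r + 1]
      }
    }
    vs[i] <- num / den
  }
  thr <- params$k_threshold * median(vs[!is.na(vs)])
  step <- 1000 / rate
  out <- list()
  last_on <- -Inf
  for (i in seq_len(n)) {
    above_i <- !is.na(vs[i]) && vs[i] > thr
    above_prev <- i > 1 && !is.na(vs[i - 1]) && vs[i - 1] > thr
    if (!above_i || above_prev) next
    t_i <- time[i]
    if (t_i - last_on < params$refractory_ms) next
    last_on <- t_i
    pre_i <- which(time >= t_i + params$pre_window_ms[1] &
                     time < t_i + params$pre_window_ms[2])
    post_i <- which(time >= t_i + params$post_window_ms[1] &
                      time < t_i + params$post_window_ms[2])
    n_pre <- round(diff(params$pre_window_ms) / step)
    n_post <- round(diff(params$post_window_ms) / step)
    if (length(pre_i) < n_pre || length(post_i) < n_post) {
      out[[length(out) + 1]] <- data.frame(onset_ms = t_i,
                                           direction = NA_real_,
                                           magnitude_deg = NA_real_,
                                           status = "unresolved")
      next
    }
    pre <- mean(x[pre_i], na.rm = TRUE)
    post <- mean(x[post_i], na.rm = TRUE)
    if (!is.finite(pre) || !is.finite(post)) {
      out[[length(out) + 1]] <- data.frame(onset_ms = t_i,
                                           direction = NA_real_,
                                           magnitude_deg = NA_real_,
                                           status = "unresolved")
      next
    }
    mag <- abs(post - pre)
    out[[length(out) + 1]] <- data.frame(
      onset_ms = t_i,
      direction = if (post - pre < 0) -1 else 1,
      magnitude_deg = mag,
      status = if (mag < params$min_magnitude_deg) "sub_minimum" else "ok")
  }
  if (!length(out))
    return(data.frame(onset_ms = numeric(), direction = numeric(),
                      magnitude_deg = numeric(), status = character()))
  do.call(rbind, out)
}

# gaze_epochs wrapper around plain vectors
ge_from_xy <- function(x, y = NULL, time = NULL, cued_side = "left",
                       task = "perception") {
  n <- length(x)
  if (is.null(y)) y <- rep(0, n)
  if (is.null(time)) time <- seq(-1000, by = 1, length.out = n)
  gaze_epochs(matrix(x, 1), matrix(y, 1), time,
              tibble::tibble(trial_id = 1, task = task,
                             cued_side = cued_side))
}

# noise-free single-saccade trace: raised cosine step of `mag` at `onset`
step_trace <- function(onset_ms, mag, dir = 1, n = 2500, t0 = -1000,
                       dur = 20) {
  time <- seq(t0, by = 1, length.out = n)
  u <- pmin(pmax((time - onset_ms) / dur, 0), 1)
  list(x = dir * mag * (1 - cos(pi * u)) / 2, time = time)
}

# interval-union oracle for blink padding: pad each zero run by pad samples
# and mark the union
mask_oracle <- function(zero, pad) {
  n <- length(zero)
  bad <- rep(FALSE, n)
  i <- 1
  while (i <= n) {
    if (zero[i]) {
      j <- i
      while (j < n && zero[j + 1]) j <- j + 1
      bad[max(1, i - pad):min(n, j + pad)] <- TRUE
      i <- j + 1
    } else i <- i + 1
  }
  bad
}

# one-way repeated-measures sums of squares computed from first principles
rm_anova_oracle <- function(m) {
  # m: participants x classes matrix
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  ss_class <- n * sum((colMeans(m) - gm)^2)
  ss_subj <- k * sum((rowMeans(m) - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_err <- ss_tot - ss_class - ss_subj
  f <- (ss_class / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  list(F = f, ss_class = ss_class, ss_err = ss_err,
       pes = ss_class / (ss_class + ss_err))
}

amps_long <- function(m, classes = colnames(m)) {
  tibble::tibble(
    participant = rep(seq_len(nrow(m)), times = ncol(m)),
    class = rep(classes, each = nrow(m)),
    value = as.vector(m))
}
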