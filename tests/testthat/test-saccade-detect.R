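test_that("velocity follows successive position differences", {
  ge <- ge_from_xy(rep(0.3, 100))
  v <- compute_velocity(ge)
  expect_true(all(v[1, -1] == 0))
  expect_true(is.na(v[1, 1]))

  x <- rep(0, 100); x[51:100] <- 0.1   # one 0.1 deg step across one sample
  v <- compute_velocity(ge_from_xy(x))
  expect_equal(v[1, 51], 100)          # deg/s at 1 kHz
  expect_true(all(v[1, -c(1, 51)] == 0))
})

test_that("a pure vertical step is invisible in 1D but not in 2D velocity", {
  y <- rep(0, 100); y[51:100] <- 0.2
  ge <- ge_from_xy(rep(0, 100), y)
  expect_true(all(compute_velocity(ge, "1d")[1, -1] == 0))
  expect_gt(max(compute_velocity(ge, "2d")[1, ], na.rm = TRUE), 0)
})

test_that("velocity smoothing preserves constants and normalizes impulses", {
  expect_equal(smooth_velocity(rep(2.5, 50)), rep(2.5, 50))
  imp <- rep(0, 51); imp[26] <- 1
  sm <- smooth_velocity(imp)
  expect_equal(sum(sm), 1)                  # kernel mass 1
  expect_equal(which.max(sm), 26)
  expect_true(all(sm[c(22, 30)] == 0))      # 7-sample support
})

test_that("smoothing reduces white-noise variance by about the kernel factor", {
  # weighted-average variance oracle: var(out) ~ sum(w^2) var(in)
  w <- exp(-(-3:3)^2 / (2 * (6 / 5)^2)); w <- w / sum(w)
  factor_oracle <- sum(w^2)
  set.seed(4)
  v <- abs(rnorm(20000))
  sm <- smooth_velocity(v)
  inner <- 10:19990
  expect_lt(var(sm[inner]), var(v[inner]))
  expect_lt(abs(var(sm[inner] - mean(v)) / var(v[inner]) - factor_oracle),
            0.25 * factor_oracle)
})

test_that("a planted noise-free saccade is recovered with onset, direction and magnitude", {
  tr <- step_trace(onset_ms = 250, mag = 0.5, dir = 1)
  # tiny jitter so the median velocity is nonzero and the threshold finite
  set.seed(1)
  ge <- ge_from_xy(tr$x + rnorm(2500, 0, 1e-4), time = tr$time)
  ev <- saccade_events(detect_saccades(ge))
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset_ms - 250), 3.5)
  expect_equal(ev$direction, 1)
  expect_lt(abs(ev$magnitude_deg - 0.5), 0.02)
})

test_that("onsets within the 100 ms refractory period are suppressed", {
  t1 <- step_trace(250, 0.4); t2 <- step_trace(310, 0.4)
  set.seed(2)
  ge <- ge_from_xy(t1$x + t2$x + rnorm(2500, 0, 1e-4), time = t1$time)
  ev <- saccade_events(detect_saccades(ge))
  expect_equal(nrow(ev), 1)           # second crossing 60 ms later discarded
  t3 <- step_trace(400, 0.4)
  ge <- ge_from_xy(t1$x + t3$x + rnorm(2500, 0, 1e-4), time = t1$time)
  expect_equal(nrow(saccade_events(detect_saccades(ge))), 2)
})

test_that("sub-minimum shifts are flagged, not returned as events", {
  tr <- step_trace(250, 0.03)
  set.seed(3)
  ge <- ge_from_xy(tr$x + rnorm(2500, 0, 1e-5), time = tr$time)
  ev <- detect_saccades(ge)
  expect_equal(nrow(saccade_events(ev)), 0)
  expect_true(any(ev$status == "sub_minimum"))
})

test_that("detection is equivariant under constant position shifts", {
  cfg <- sim_config(n_participants = 1, trials_per_task = 5, seed = 5)
  sim <- simulate_participant(cfg, 1)
  ge <- mask_blinks(sim$gaze)
  ge2 <- ge
  ge2$x <- ge2$x + 3.7
  ev1 <- detect_saccades(ge)
  ev2 <- detect_saccades(ge2)
  expect_equal(ev1, ev2)
})

test_that("detector matches the naive rule-replay oracle on random traces", {
  set.seed(11)
  for (rep in 1:100) {
    n <- 700
    x <- cumsum(rnorm(n, 0, 2e-4)) + rnorm(n, 0, 2e-3)
    n_sacc <- sample(0:3, 1)
    for (s in seq_len(n_sacc)) {
      tr <- step_trace(runif(1, -200, 500), runif(1, 0.02, 0.8),
                       sample(c(-1, 1), 1), n = n, t0 = -350)
      x <- x + tr$x
    }
    time <- seq(-350, by = 1, length.out = n)
    if (runif(1) < 0.3) x[sample(n - 60, 1) + 0:50] <- NA  # masked gap
    ge <- ge_from_xy(x, time = time)
    got <- detect_saccades(ge)
    want <- naive_detect(x, time)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$onset_ms, want$onset_ms)
      expect_equal(got$status, want$status)
      ok <- got$status == "ok"
      expect_equal(got$direction[ok], want$direction[ok])
      expect_equal(got$magnitude_deg[ok], want$magnitude_deg[ok])
    }
  }
})

test_that("threshold sweep is monotone and saturates for strong saccades", {
  # pure noise: event count non-increasing in k
  set.seed(7)
  x <- cumsum(rnorm(2500, 0, 3e-4)) + rnorm(2500, 0, 3e-3)
  ge <- ge_from_xy(x)
  sw <- threshold_sweep(ge, k_values = c(2, 3, 4, 5))
  expect_true(all(diff(sw$n_events) <= 0))
  # unreachable threshold: no events
  sw_inf <- threshold_sweep(ge, k_values = 1e6)
  expect_equal(sw_inf$n_events, 0L)
  # planted strong saccades dominate every threshold in the sweep
  tr <- step_trace(250, 0.8)
  set.seed(8)
  ge2 <- ge_from_xy(tr$x + rnorm(2500, 0, 1e-4), time = tr$time)
  sw2 <- threshold_sweep(ge2, k_values = c(2, 3, 4, 5))
  expect_true(all(sw2$n_events == 1L))
  # larger k events are a subset of smaller k events (noise-free contract)
  on3 <- sw2$events[[2]]$onset_ms
  on5 <- sw2$events[[4]]$onset_ms
  expect_true(all(on5 %in% on3))
})
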