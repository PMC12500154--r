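mk_eeg4 <- function(data, cued, rate = 1024) {
  eeg_epochs(data, c("PO7", "PO8", "Oz", "HEOG"), rate,
             seq(-1000, by = 1000 / rate, length.out = dim(data)[3]),
             tibble::tibble(trial_id = seq_len(dim(data)[1]),
                            cued_side = cued))
}

sine_epochs <- function(amp_po7, amp_po8, freq = 10, n = 2560,
                        cued = c("left", "right"), phase = 0) {
  tm <- seq(-1000, by = 1000 / 1024, length.out = n)
  osc <- sin(2 * pi * freq * tm / 1000 + phase)
  d <- array(0, c(length(cued), 4, n))
  for (i in seq_along(cued)) {
    d[i, 1, ] <- amp_po7 * osc
    d[i, 2, ] <- amp_po8 * osc
  }
  mk_eeg4(d, cued)
}

test_that("STFT power concentrates at the driving frequency and scales quadratically", {
  ep <- sine_epochs(1, 1)
  pw <- stft_power(ep)
  p_mean <- apply(pw$power[, 1, , ], 2, mean)   # PO7, average over time
  expect_equal(pw$freqs[which.max(p_mean)], 10)
  expect_gt(p_mean[pw$freqs == 10], 50 * mean(p_mean[abs(pw$freqs - 10) > 3]))
  ep2 <- sine_epochs(2, 2)
  pw2 <- stft_power(ep2)
  expect_equal(apply(pw2$power[, 1, , ], 2, mean)[pw$freqs == 10],
               4 * p_mean[pw$freqs == 10], tolerance = 1e-6)
  expect_error(stft_power(ep, freqs = 3:600), "Nyquist")
})

test_that("white-noise power is flat across frequencies", {
  set.seed(41)
  d <- array(rnorm(40 * 4 * 2560), c(40, 4, 2560))
  pw <- stft_power(mk_eeg4(d, rep(c("left", "right"), 20)))
  # per-frequency mean with an empirical SE over trials
  m_trial <- apply(pw$power[, 1, , ], c(1, 2), mean)  # trials x freq
  m <- colMeans(m_trial)
  se <- apply(m_trial, 2, sd) / sqrt(nrow(m_trial))
  expect_true(all(abs(m - mean(m)) < 3.5 * se))
})

test_that("lateralization index has the right fixed points and bounds", {
  # contra == ipsi -> 0 everywhere
  ep <- sine_epochs(1, 1, cued = c("left", "right"))
  li <- lateralization_index(stft_power(ep))
  expect_true(all(abs(li$lat[li$freq == 10]) < 1e-9))
  # one-sided designs are refused
  ep2 <- sine_epochs(amp_po7 = 1, amp_po8 = 0, cued = c("left", "left"))
  expect_error(lateralization_index(stft_power(ep2)), "both cued sides")
  # zero contralateral power pins the index at its -100 bound
  d <- array(0, c(2, 4, 2560))
  tm <- seq(-1000, by = 1000 / 1024, length.out = 2560)
  osc <- sin(2 * pi * 10 * tm / 1000)
  d[1, 1, ] <- osc  # left-cued: ipsi (PO7) active, contra (PO8) silent
  d[2, 2, ] <- osc  # right-cued: ipsi (PO8) active, contra (PO7) silent
  li4 <- lateralization_index(stft_power(mk_eeg4(d, c("left", "right"))))
  expect_true(all(abs(li4$lat[li4$freq == 10] + 100) < 1e-6))
  expect_true(all(li4$lat >= -100 - 1e-9 & li4$lat <= 100 + 1e-9,
                  na.rm = TRUE))
})

test_that("planted amplitude ratio follows the closed-form index", {
  # contra:ipsi amplitude ratio r gives L = 100 (r^2 - 1) / (r^2 + 1)
  r <- 0.8
  d <- array(0, c(2, 4, 2560))
  tm <- seq(-1000, by = 1000 / 1024, length.out = 2560)
  osc <- sin(2 * pi * 10 * tm / 1000)
  # left-cued: contra is PO8; right-cued: contra is PO7
  d[1, 2, ] <- r * osc; d[1, 1, ] <- osc
  d[2, 1, ] <- r * osc; d[2, 2, ] <- osc
  li <- lateralization_index(stft_power(mk_eeg4(d, c("left", "right"))))
  got <- mean(li$lat[li$freq == 10])
  expect_equal(got, 100 * (r^2 - 1) / (r^2 + 1), tolerance = 1e-6)
  # antisymmetry: swapping cued sides negates L
  li2 <- lateralization_index(stft_power(mk_eeg4(d, c("right", "left"))))
  expect_equal(li2$lat, -li$lat, tolerance = 1e-9)
})

test_that("the alpha summary defaults cover 8-12 Hz and 400-800 ms", {
  expect_equal(eval(formals(alpha_lateralization)$freq_band), c(8, 12))
  expect_equal(eval(formals(alpha_lateralization)$time_window), c(400, 800))
  li <- tibble::tibble(freq = rep(c(8, 10, 12, 20), each = 2),
                       time_ms = rep(c(500, 900), 4),
                       contra = 1, ipsi = 1,
                       lat = rep(c(-30, 99), 4))
  # only the in-band, in-window cells (-30 at 8/10/12 Hz, 500 ms) count
  expect_equal(alpha_lateralization(li), -30)
})

test_that("the generator's planted alpha asymmetry is recovered through the index", {
  cfg <- sim_config(n_participants = 1, trials_per_task = 6, noise_sd = 0,
                    n2pc_amp_by_class = c(toward = 0, none = 0, away = 0),
                    bg_rate_hz = 0, blink_prob = 0, drift_sd = 0,
                    gaze_noise_sd = 0, p_toward = 0, p_away = 0, p_none = 1,
                    seed = 44)
  sim <- simulate_participant(cfg, 1)
  li <- lateralization_index(stft_power(sim$eeg))
  d <- cfg$alpha_lat_amp
  r <- (1 - d) / (1 + d)
  got <- alpha_lateralization(li)
  expect_equal(got, 100 * (r^2 - 1) / (r^2 + 1), tolerance = 0.02)
})
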