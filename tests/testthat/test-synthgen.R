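test_that("configuration invariants are enforced", {
  expect_error(sim_config(p_toward = 0.5, p_away = 0.5, p_none = 0.5),
               "sum to 1")
  expect_error(sim_config(gaze_rate = 0), "positive")
  expect_error(sim_config(saccade_bias_window = c(150, 2000)), "outside")
  expect_error(sim_config(channels = c("PO7", "PO8")), "must include")
  cfg <- sim_config()
  expect_equal(cfg$n_participants, 23)
  expect_equal(cfg$trials_per_task, 600)
  expect_equal(cfg$object_eccentricity, 5)
  expect_equal(cfg$epoch_window, c(-1000, 1500))
})

test_that("a fixed seed reproduces the experiment exactly", {
  cfg <- sim_config(n_participants = 2, trials_per_task = 10, seed = 5)
  a <- simulate_participant(cfg, 1)
  b <- simulate_participant(cfg, 1)
  expect_identical(a$gaze$x, b$gaze$x)
  expect_identical(a$eeg$data, b$eeg$data)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_participant(cfg, 2)
  expect_false(identical(a$gaze$x, c2$gaze$x))
})

test_that("cued sides are balanced and both tasks appear", {
  cfg <- sim_config(n_participants = 1, trials_per_task = 21, seed = 6)
  sim <- simulate_participant(cfg, 1)
  for (tk in c("perception", "wm")) {
    sides <- sim$metadata$cued_side[sim$metadata$task == tk]
    expect_lte(abs(sum(sides == "left") - sum(sides == "right")), 1)
  }
})

test_that("degenerate class mixes behave as planted", {
  cfg <- sim_config(n_participants = 1, trials_per_task = 30, seed = 7,
                    p_toward = 0, p_away = 0, p_none = 1)
  sim <- simulate_participant(cfg, 1)
  sacc <- sim$truth$saccades
  expect_false(any(sacc$onset_ms >= 150 & sacc$onset_ms < 400))
  expect_true(all(sim$metadata$class_true == "none"))
})

test_that("the noise-free limit produces a constant no-saccade trace", {
  cfg <- sim_config(drift_sd = 0, gaze_noise_sd = 0, blink_prob = 0,
                    bg_rate_hz = 0, seed = 8)
  g <- simulate_gaze_trial("none", "left", cfg, seed = 1)
  expect_equal(diff(range(g$x)), 0)
  expect_equal(diff(range(g$y)), 0)
})

test_that("planted displacement is readable from the trace and sign convention holds", {
  cfg <- sim_config(drift_sd = 0, gaze_noise_sd = 0, blink_prob = 0,
                    bg_rate_hz = 0, sacc_mag_range = c(0.5, 0.5), seed = 9)
  g <- simulate_gaze_trial("toward", "left", cfg, seed = 2)
  s <- g$saccades
  expect_equal(s$direction, -1)      # toward a left cue is leftward
  expect_gte(s$magnitude_deg, 0.1)
  i_on <- which(g$time_ms == s$onset_ms)
  pre <- mean(g$x[(i_on - 50):(i_on - 1)])
  post <- mean(g$x[(i_on + 50):(i_on + 100)])
  expect_equal(post - pre, -0.5, tolerance = 1e-9)
  g2 <- simulate_gaze_trial("away", "left", cfg, seed = 2)
  expect_equal(g2$saccades$direction, 1)
})

test_that("noise-free EEG contains exactly the planted components", {
  cfg <- sim_config(noise_sd = 0, alpha_amp = 0, drift_sd = 0,
                    gaze_noise_sd = 0, blink_prob = 0, bg_rate_hz = 0,
                    seed = 10)
  # no-saccade trial: PO7 - PO8 difference is exactly the planted bump
  e <- simulate_eeg_trial("none", "left",
                          tibble::tibble(onset_ms = numeric(),
                                         direction = numeric(),
                                         magnitude_deg = numeric()),
                          cfg, seed = 3)
  tm <- seq(-1000, by = 1000 / 1024, length.out = ncol(e))
  widx <- tm >= 200 & tm < 300
  # contralateral channel to a left cue is PO8; window mean equals the
  # configured class amplitude
  expect_equal(mean(e["PO8", widx]), cfg$n2pc_amp_by_class[["none"]],
               tolerance = 1e-9)
  expect_true(all(e["PO7", ] == 0))
  expect_true(all(e["HEOG", ] == 0))
  # a planted saccade at +250 ms puts the lambda peak at 250 + delay on Oz
  sacc <- tibble::tibble(onset_ms = 250, direction = 1, magnitude_deg = 0.5)
  e2 <- simulate_eeg_trial("none", "left", sacc, cfg, seed = 3)
  expect_equal(tm[which.max(e2["Oz", ])], 250 + cfg$lambda_delay_ms,
               tolerance = 1)
  # HEOG step sign follows the saccade direction and scales with eog_gain
  expect_equal(unname(e2["HEOG", length(tm)]), cfg$eog_gain * 0.5,
               tolerance = 1e-9)
  # mirroring: swapping cued_side swaps the lateralized channels exactly
  e3 <- simulate_eeg_trial("none", "right", sacc, cfg, seed = 3)
  expect_equal(e3["PO7", ], e2["PO8", ])
  expect_equal(e3["PO8", ], e2["PO7", ])
})

test_that("trial-averaged recovery of the planted window amplitude obeys the CLT", {
  cfg <- sim_config(n_participants = 1, trials_per_task = 100,
                    p_toward = 0, p_away = 0, p_none = 1,
                    n2pc_amp_sd = 0, blink_prob = 0, seed = 12)
  sim <- simulate_participant(cfg, 1)
  eeg <- baseline_correct(sim$eeg)
  w <- contra_ipsi(eeg)
  amp <- n2pc_amplitude(w)
  # CLT oracle on the configured noise: the windowed mean of the
  # difference of two channels across n trials
  n <- nrow(sim$metadata)
  se_trial <- sd(apply(trialwise_diff(eeg)[,
                  eeg$time_ms >= 200 & eeg$time_ms < 300], 1, mean)) / sqrt(n)
  expect_lt(abs(amp - cfg$n2pc_amp_by_class[["none"]]), 3 * se_trial)
})

test_that("background saccade rate does not depend on the class label", {
  cfg <- sim_config(seed = 13)
  counts <- function(cl) {
    vapply(1:250, function(i) {
      s <- simulate_gaze_trial(cl, "left", cfg, seed = 1000 + i)$saccades
      as.numeric(sum(!s$in_window))
    }, numeric(1))
  }
  n_none <- counts("none")
  n_tow <- counts("toward")
  tt <- t.test(n_none, n_tow)
  expect_gt(tt$p.value, 0.001)
  expect_lt(abs(mean(n_none) - mean(n_tow)), 0.35)
})

test_that("written datasets round-trip through the package readers", {
  cfg <- sim_config(n_participants = 2, trials_per_task = 4, seed = 14)
  dir <- tempfile()
  out <- simulate_experiment(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  sim1 <- simulate_participant(cfg, 1)
  md <- readr::read_csv(file.path(dir, "metadata.csv"),
                        show_col_types = FALSE)
  ge <- read_gaze_table(file.path(dir, "gaze_p01.csv"),
                        metadata = md[md$participant == 1, ])
  expect_equal(ge$x, sim1$gaze$x, tolerance = 1e-12)
  ep <- read_eeg_epochs(file.path(dir, "eeg_p01"))
  expect_identical(ep$data, sim1$eeg$data)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(length(truth$saccades$onset_ms), nrow(out$truth$saccades))
  unlink(dir, recursive = TRUE)
})
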