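mk_eeg <- function(data, cued, rate = 1024) {
  nt <- dim(data)[1]
  eeg_epochs(data, c("PO7", "PO8", "Oz", "HEOG"), rate,
             seq(-1000, by = 1000 / rate, length.out = dim(data)[3]),
             tibble::tibble(trial_id = seq_len(nt), cued_side = cued))
}

test_that("baseline correction zeroes the baseline mean and is idempotent", {
  d <- array(5, c(2, 4, 2560))
  ep <- mk_eeg(d, c("left", "right"))
  bc <- baseline_correct(ep)
  expect_true(all(bc$data == 0))
  d2 <- array(rnorm(2 * 4 * 2560), c(2, 4, 2560))
  ep2 <- baseline_correct(mk_eeg(d2, c("left", "right")))
  idx <- which(ep2$time_ms >= -250 & ep2$time_ms < 0)
  expect_lt(max(abs(apply(ep2$data[, , idx], c(1, 2), mean))), 1e-9)
  ep3 <- baseline_correct(ep2)
  expect_equal(ep3$data, ep2$data)
  expect_error(baseline_correct(ep2, c(-2000, 0)), "outside")
})

test_that("a planted contralateral bump appears in the difference wave", {
  n <- 2560
  tm <- seq(-1000, by = 1000 / 1024, length.out = n)
  bump <- -1 * exp(-(tm - 250)^2 / (2 * 20^2))
  d <- array(0, c(2, 4, n))
  d[1, 2, ] <- bump   # left-cued trial: PO8 is contralateral
  d[2, 1, ] <- bump   # right-cued trial: PO7 is contralateral
  ep <- mk_eeg(d, c("left", "right"))
  w <- contra_ipsi(ep, smooth_sd = 0)
  expect_equal(w$diff, bump)
  expect_equal(min(w$diff), -1, tolerance = 1e-6)
  # swapping the cued-side labels negates the difference wave
  ep2 <- ep
  ep2$metadata$cued_side <- c("right", "left")
  w2 <- contra_ipsi(ep2, smooth_sd = 0)
  expect_equal(w2$diff, -w$diff)
  # one-sided designs are refused with the side named
  ep3 <- mk_eeg(d[1, , , drop = FALSE], "left")
  expect_error(contra_ipsi(ep3), "right")
})

test_that("windowed N2pc amplitude is the window mean and is linear", {
  tm <- seq(-1000, by = 1, length.out = 2500)
  w <- tibble::tibble(time_ms = tm, contra = 0, ipsi = 2, diff = -2)
  class(w) <- c("lateralized_wave", class(w))
  expect_equal(n2pc_amplitude(w), -2)
  # antisymmetric wave around 250 ms averages to zero over [200, 300)
  w2 <- w
  w2$diff <- tm - 250
  expect_equal(n2pc_amplitude(w2), mean((200:299) - 250))
  expect_equal(n2pc_amplitude(w2), -0.5)  # independent arithmetic check
  # linearity
  w3 <- w
  w3$diff <- rnorm(2500)
  a <- n2pc_amplitude(w3)
  w3$diff <- 3.5 * w3$diff
  expect_equal(n2pc_amplitude(w3), 3.5 * a)
  # quadrature oracle: equals the plain mean over the window samples
  idx <- which(tm >= 200 & tm < 300)
  expect_equal(n2pc_amplitude(w3), mean(w3$diff[idx]))
})

test_that("smoothing preserves window means away from edges", {
  set.seed(31)
  n <- 2560
  d <- array(rnorm(2 * 4 * n), c(2, 4, n))
  ep <- mk_eeg(d, c("left", "right"))
  w_raw <- contra_ipsi(ep, smooth_sd = 0)
  w_sm <- contra_ipsi(ep, smooth_sd = 15)
  win <- c(-200, 300)  # >= 10 SD wide, interior
  expect_lt(abs(n2pc_amplitude(w_sm, win) - n2pc_amplitude(w_raw, win)),
            0.02)
})

test_that("class-weighted difference waves reassemble the all-trials wave", {
  set.seed(32)
  n <- 512
  d <- array(rnorm(12 * 4 * n), c(12, 4, n))
  cued <- rep(c("left", "right"), 6)
  cls <- rep(c("toward", "none", "away"), each = 4)
  ep <- mk_eeg(d, cued)
  w_all <- contra_ipsi(ep, smooth_sd = 0)
  acc <- 0
  for (cl in unique(cls)) {
    sel <- which(cls == cl)
    acc <- acc + length(sel) * contra_ipsi(subset_trials(ep, sel),
                                           smooth_sd = 0)$diff
  }
  expect_equal(acc / 12, w_all$diff)
})

test_that("grand averages weight participants equally", {
  tm <- 1:10
  mk <- function(v) {
    w <- tibble::tibble(time_ms = tm, contra = v, ipsi = 0, diff = v)
    class(w) <- c("lateralized_wave", class(w)); w
  }
  ga <- grand_average(list(mk(rep(1, 10)), mk(rep(3, 10))))
  expect_equal(ga$diff, rep(2, 10))
})

test_that("EEG epochs round-trip losslessly through the array container", {
  set.seed(33)
  d <- array(rnorm(3 * 4 * 100), c(3, 4, 100))
  ep <- mk_eeg(d, c("left", "right", "left"))
  pre <- tempfile()
  write_eeg_epochs(ep, pre)
  back <- read_eeg_epochs(pre)
  expect_identical(back$data, ep$data)
  expect_equal(back$channels, ep$channels)
  expect_equal(back$time_ms, ep$time_ms)
  expect_equal(back$metadata$cued_side, ep$metadata$cued_side)
})
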