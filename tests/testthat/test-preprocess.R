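make_rec <- function(signal) {
  C <- nrow(signal)
  geom <- electrode_geometry(matrix(seq_len(3 * C), C, 3), anode_index = 1)
  sched <- make_schedule(frequencies = 10, amplitudes = 1, reps = 1,
                         start_ms = 2000, seed = 1)
  recording(signal, geom, sched)
}

test_that("preprocess: notch attenuation, detrend, z-score, idempotence", {
  set.seed(42)
  n <- 8000
  t <- seq_len(n)
  x <- sin(2 * pi * 60 * t / 1000) + rnorm(n, sd = 0.3)
  rec <- make_rec(rbind(x, 0.002 * t + rnorm(n, sd = 0.1)))
  pp <- preprocess_signal(rec)
  # >= 20 dB power reduction at 60 Hz
  p_before <- power_at(x, 60)
  p_after <- power_at(pp$signal[1, ] * sd(x), 60)
  expect_gt(10 * log10(p_before / p_after), 20)
  # z-scored output
  for (k in 1:2) {
    expect_lt(abs(mean(pp$signal[k, ])), 1e-9)
    expect_lt(abs(sd(pp$signal[k, ]) - 1), 1e-9)
  }
  # ramp channel: no residual linear trend
  slope <- coef(lm(pp$signal[2, ] ~ t))[2]
  expect_lt(abs(slope), 1e-9)
  # z-scoring twice changes nothing
  x2 <- pp$signal[2, ]
  expect_equal((x2 - mean(x2)) / sd(x2), x2, tolerance = 1e-6)
})

test_that("preprocess passes through already-standardized white noise", {
  set.seed(7)
  x <- as.numeric(scale(rnorm(6000)))
  pp <- preprocess_signal(make_rec(rbind(x, x)))
  expect_gt(cor(pp$signal[1, ], x), 0.99)
})

test_that("constant channel is flagged and skipped with a warning", {
  x <- rnorm(4000)
  expect_warning(pp <- preprocess_signal(make_rec(rbind(x, rep(2, 4000)))),
                 "constant")
  expect_identical(attr(pp, "constant_channels"), 2L)
})

test_that("input encoding matches the integer-multiples rule", {
  ev <- function(f, a, t0) data.frame(onset = t0, duration_ms = 500L,
                                      freq_hz = f, amp_ma = a)
  u <- encode_input(ev(10, 2, 0), 1000)
  expect_identical(which(u != 0) - 1L, as.integer(c(0, 100, 200, 300, 400,
                                                    500)))
  expect_true(all(u[u != 0] == 2))

  u200 <- encode_input(ev(200, 1, 0), 1000)
  expect_identical(sum(u200 != 0), 101L)
  expect_identical(which(u200 != 0) - 1L, as.integer(seq(0, 500, by = 5)))

  usp <- encode_input(ev(-1, 1, 50), 200)
  expect_identical(which(usp != 0) - 1L, 50L)
  expect_identical(usp[51], 1)

  expect_error(encode_input(ev(33, 1, 0), 1000), "allowed")

  # brute-force enumeration property over all pulse-train frequencies
  for (f in setdiff(STIM_FREQUENCIES, -1)) {
    u <- encode_input(ev(f, 1, 100), 2000)
    expected <- sum((0:500) %% (1000 / f) == 0)
    expect_identical(sum(u != 0), as.integer(expected))
    expect_identical(expected, as.integer(floor(500 * f / 1000) + 1))
  }
})

test_that("gating signal modes", {
  ev <- data.frame(onset = 100L, duration_ms = 500L, freq_hz = 25,
                   amp_ma = 1.5)
  u <- encode_input(ev, 1000)
  Us <- gating_signal(u, ev, "switched")
  expect_identical(sum(Us == 1), 501L)
  expect_true(all(Us[101:601] == 1))
  expect_true(all(Us[c(1:100, 602:1000)] == 0))
  Ua <- gating_signal(u, ev, "amplitude")
  expect_true(all(Ua[101:601] == 1.5))
  expect_identical(gating_signal(u, ev, "bilinear"), u)
  expect_identical(gating_signal(u, ev, "none"), numeric(1000))
  expect_error(gating_signal(u, ev, "what"), "arg")
})

test_that("onset correction recovers a planted delivery delay", {
  w <- quick_world(seed = 21, C = 2, L = 2, M = 2, family = "ARX",
                   frequencies = 50, reps = 4, noise_sd = 0.05)
  # deliver 15 ms later than reported: shift reported onsets back by 15
  ev_reported <- w$sched$events
  ev_reported$onset <- ev_reported$onset - 15L
  corr <- correct_onsets(w$rec, ev_reported, threshold_mult = 4)
  expect_true(all(!corr$flagged))
  expect_true(all(abs(corr$delay_ms - 15) <= 1))
  expect_identical(corr$events$onset, w$sched$events$onset)

  # clean zero-delay: onsets unchanged
  corr0 <- correct_onsets(w$rec, w$sched$events, threshold_mult = 4)
  expect_true(all(abs(corr0$delay_ms[!corr0$flagged]) <= 1))

  # flat anode: everything flagged, nothing adjusted
  flat <- w$rec
  flat$signal[1, ] <- 0
  corrf <- correct_onsets(flat, w$sched$events)
  expect_true(all(corrf$flagged))
  expect_identical(corrf$events$onset, w$sched$events$onset)
})

test_that("window extraction layout, fold tiling, and edge skipping", {
  w <- quick_world(seed = 3, C = 1, frequencies = c(10, 200), reps = 2)
  ev <- data.frame(onset = c(5000L, 9000L), duration_ms = 500L,
                   freq_hz = c(25, -1), amp_ma = 1)
  ws <- extract_windows_and_folds(w$rec, events = ev, seed = 4)
  expect_identical(ws$windows$start, c(4500L, 8250L))
  expect_identical(ws$windows$end, c(6000L, 9750L))
  # folds tile each window exactly
  for (i in 1:2) {
    f <- stimdyn:::fold_of_sample(ws, i,
                                  ws$windows$start[i]:(ws$windows$end[i] - 1))
    expect_identical(as.integer(table(f)), rep(300L, 5))
  }
  expect_true(all(ws$windows$test_fold %in% 1:5))

  ev_edge <- rbind(ev, data.frame(onset = 100L, duration_ms = 500L,
                                  freq_hz = 25, amp_ma = 1))
  expect_warning(ws2 <- extract_windows_and_folds(w$rec, events = ev_edge,
                                                  seed = 4),
                 "skipped")
  expect_equal(nrow(ws2$windows), 2L)
  expect_error(
    suppressWarnings(
      extract_windows_and_folds(w$rec,
                                events = ev_edge[3, , drop = FALSE])),
    "no extractable")
})
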