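test_that("electrode geometry: degenerate, exact distance, reproducibility", {
  g1 <- make_electrode_geometry(1, 100, seed = 3)
  expect_equal(dim(g1$pairwise_dist), c(1L, 1L))
  expect_identical(g1$pairwise_dist[1, 1], 0)

  g2 <- electrode_geometry(rbind(c(0, 0, 0), c(3, 4, 0)), anode_index = 1)
  expect_equal(g2$pairwise_dist[1, 2], 5)
  expect_true(isSymmetric(g2$pairwise_dist))
  expect_true(all(diag(g2$pairwise_dist) == 0))

  ga <- make_electrode_geometry(30, 150, seed = 7)
  gb <- make_electrode_geometry(30, 150, seed = 7)
  expect_identical(ga$coords, gb$coords)
  expect_error(make_electrode_geometry(0, 100), "n_channels")
})

test_that("ground-truth systems honor family, margin and coupling band", {
  geom <- make_electrode_geometry(6, 120, seed = 1)
  sys_ar <- sample_ground_truth_system(
    model_spec(1, L = 4, M = 3, P = 2, family = "AR"), geom, seed = 2)
  expect_true(all(sys_ar$b == 0))
  expect_true(all(sys_ar$c == 0))
  expect_true(all(sys_ar$d == 0))

  sys_sw <- sample_ground_truth_system(
    model_spec(1, L = 5, M = 2, P = 1, family = "SL_VARX",
               gating = "switched"),
    geom, margin = 0.95, seed = 3)
  for (k in 1:6) {
    expect_lte(stimdyn:::companion_radius(sys_sw$a[, k]), 0.95 + 1e-8)
    expect_lte(stimdyn:::companion_radius(sys_sw$a[, k] + sys_sw$c[, k]),
               0.95 + 1e-8)
  }

  band <- c(40, 80)
  sys_bd <- sample_ground_truth_system(
    model_spec(1, L = 3, M = 0, P = 1, family = "VAR"),
    geom, coupling_band = band, seed = 4)
  for (k in 1:6) for (i in 1:6) {
    if (i == k) next
    dd <- geom$pairwise_dist[k, i]
    if (!(dd > band[1] && dd < band[2]))
      expect_true(all(sys_bd$d[k, i, ] == 0))
  }
})

test_that("schedules: factorial counts, amplitude levels, overlap guard", {
  s <- make_schedule(frequencies = STIM_FREQUENCIES, reps = 20,
                     gap_ms = 1500, A_safe = 2.0, seed = 1)
  expect_equal(nrow(s$events), 6 * 3 * 20)
  expect_setequal(unique(s$events$amp_ma), c(2.0, 1.75, 1.5))
  cnt <- table(s$events$freq_hz, s$events$amp_ma)
  expect_true(all(cnt == 20))
  expect_true(all(diff(sort(s$events$onset)) >= 500 + 1500))

  s1 <- make_schedule(frequencies = 10, amplitudes = 1, reps = 1, seed = 2)
  expect_equal(nrow(s1$events), 1L)
  expect_error(make_schedule(gap_ms = 500), "gap")
  expect_error(make_schedule(frequencies = c(10, 33)), "subset")
})

test_that("simulation: zero world, hand recursion, boundedness, seeds", {
  geom <- make_electrode_geometry(1, 10, seed = 1)
  # zero noise, zero input, zero state -> identically zero
  spec <- model_spec(1, L = 1, M = 1, family = "ARX")
  sys <- sample_ground_truth_system(spec, geom, noise_sd = 0, seed = 1)
  sched0 <- make_schedule(frequencies = -1, amplitudes = 0, reps = 1,
                          seed = 1)
  rec0 <- simulate_recording(sys, sched0, seed = 1)
  expect_true(all(rec0$signal == 0))

  # L=1 scalar a=-0.1, unit b (M=1), single unit pulse: hand recursion
  sys$a[1, 1] <- -0.1
  sys$b[1, 1] <- 1
  sys$c[] <- 0
  sched1 <- make_schedule(frequencies = -1, amplitudes = 1, reps = 1,
                          start_ms = 2000, seed = 1)
  rec1 <- simulate_recording(sys, sched1, seed = 1)
  T_total <- rec1$T
  u <- encode_input(sched1, T_total)
  yh <- numeric(T_total)
  for (s in 2:(T_total - 1))
    yh[s + 1] <- yh[s] - 0.1 * yh[s - 1] + 1 * u[s - 1]
  expect_equal(rec1$signal[1, ], yh, tolerance = 1e-12)
  expect_gt(max(abs(rec1$signal)), 0)

  # stable stochastic system stays bounded over a long run
  w <- quick_world(seed = 9, C = 2, frequencies = c(10, 200), reps = 2)
  long <- simulate_recording(w$sys, w$sched,
                             duration_samples = 60000, seed = 9)
  expect_lt(max(abs(long$signal)), 50)

  # seed determinism
  r1 <- simulate_recording(w$sys, w$sched, seed = 11)
  r2 <- simulate_recording(w$sys, w$sched, seed = 11)
  expect_identical(r1$signal, r2$signal)
})

test_that("STIM OFF segments of a switched system realize the a-only law", {
  # refitting on OFF-only samples recovers a_k
  w <- quick_world(seed = 5, C = 1, L = 3, M = 2, family = "SL_ARX",
                   reps = 6, noise_sd = 0.1)
  ds <- build_features(w$rec, w$ws, model_spec(1, L = 3, M = 0,
                                               family = "AR"))
  off <- !stimdyn:::stim_on_mask(w$sched$events, w$rec$T)[ds$t + 2L]
  m <- fit_ridge(ds, lambda = 1e-8, rows = off & !ds$is_test)
  expect_lt(max(abs(m$theta - w$sys$a[, 1])), 0.06)
})

test_that("switched output is amplitude-invariant; amplitude-weighted is not", {
  geom <- make_electrode_geometry(1, 10, seed = 1)
  base <- model_spec(1, L = 2, M = 0, family = "SL_AR", gating = "switched")
  sys <- sample_ground_truth_system(base, geom, noise_sd = 0, seed = 2)
  sys$a[, 1] <- c(-0.3, 0.1); sys$c[, 1] <- c(-0.2, 0.05)
  # early onsets so stimulation overlaps the decaying initial state
  # (no input block and no noise: activity only comes from the init)
  mk <- function(amp) make_schedule(frequencies = 50, amplitudes = amp,
                                    reps = 2, start_ms = 10, seed = 3)
  init <- matrix(0.5, 1, 3)
  y_hi <- simulate_recording(sys, mk(2.0), init = init, seed = 4)$signal
  y_lo <- simulate_recording(sys, mk(1.0), init = init, seed = 4)$signal
  expect_equal(y_hi, y_lo, tolerance = 1e-12)

  sys$gating <- "amplitude"
  ya_hi <- simulate_recording(sys, mk(2.0), init = init, seed = 4)$signal
  ya_lo <- simulate_recording(sys, mk(1.0), init = init, seed = 4)$signal
  expect_gt(max(abs(ya_hi - ya_lo)), 1e-6)
})

test_that("recording container and ground-truth sidecar round-trip", {
  tdir <- withr::local_tempdir()
  for (s in 1:3) {
    w <- quick_world(seed = s, C = 3, L = 2, M = 1, P = 1,
                     family = "SL_VARX", frequencies = c(10, 200),
                     reps = 1)
    p <- file.path(tdir, paste0("rec", s))
    write_recording(w$rec, p)
    back <- read_recording(p)
    expect_equal(back$signal, w$rec$signal, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_identical(back$schedule$events$onset, w$rec$schedule$events$onset)
    expect_equal(back$schedule$events$amp_ma, w$rec$schedule$events$amp_ma)
    expect_equal(back$geometry$coords, w$rec$geometry$coords,
                 tolerance = 1e-12, ignore_attr = TRUE)

    gt <- file.path(tdir, paste0("gt", s, ".json"))
    write_ground_truth(w$sys, gt)
    sys2 <- read_ground_truth(gt, w$geom)
    expect_equal(sys2$a, w$sys$a, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(sys2$d, w$sys$d, tolerance = 1e-12)
    expect_identical(sys2$family, w$sys$family)
  }
  expect_error(read_recording(file.path(tdir, "nope")), "missing")
})
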