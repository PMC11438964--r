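test_that("feature construction is exact bookkeeping", {
  # hand-built example: y = 1..8 in one window, L = 2
  geom <- electrode_geometry(matrix(0, 1, 3))
  sched <- make_schedule(frequencies = 10, amplitudes = 1, reps = 1,
                         start_ms = 2000, seed = 1)
  y <- matrix(as.numeric(seq_len(6000)), 1)
  rec <- recording(y, geom, sched)
  ws <- extract_windows_and_folds(rec, seed = 1)
  ds <- build_features(rec, ws, model_spec(1, L = 2, family = "AR"))
  i <- 1L
  t0 <- ds$t[i]                     # first valid sample (0-based)
  expect_identical(ds$X[i, ], c(y[1, t0], y[1, t0 - 1]))
  expect_identical(ds$dy[i], y[1, t0 + 2] - y[1, t0 + 1])
  # reconstructing y(t+1) from features + target is lossless
  expect_equal(ds$y_t + ds$dy, y[1, ds$t + 2], ignore_attr = TRUE)
  # history stays inside the window
  expect_true(all(ds$t - 2 >= ws$windows$start[ds$window]))
  expect_true(all(ds$t + 1 < ws$windows$end[ds$window]))
})

test_that("switched interaction block is zero during STIM OFF", {
  w <- quick_world(seed = 2, C = 1, L = 3, M = 2, family = "SL_ARX",
                   frequencies = 50, reps = 2)
  ds <- build_features(w$rec, w$ws, w$spec)
  on <- stimdyn:::stim_on_mask(w$sched$events, w$rec$T)[ds$t + 1L]
  ccols <- ds$blocks$c
  expect_true(all(ds$X[!on, ccols] == 0))
  expect_false(all(ds$X[on, ccols] == 0))
})

test_that("sparse specs use delay-embedded lags; tau = 1 equals dense", {
  geom <- electrode_geometry(matrix(0, 1, 3))
  sched <- make_schedule(frequencies = 10, amplitudes = 1, reps = 1,
                         start_ms = 2000, seed = 1)
  y <- matrix(sin(seq_len(6000) / 7), 1)
  rec <- recording(y, geom, sched)
  ws <- extract_windows_and_folds(rec, seed = 1)
  sp_sparse <- model_spec(1, L = 2, family = "AR", sparse = TRUE, tau = 3)
  ds <- build_features(rec, ws, sp_sparse)
  i <- 5L
  s <- ds$t[i] + 1L
  expect_identical(ds$X[i, ], c(y[1, s - 3], y[1, s - 6]))

  ds1 <- build_features(rec, ws, model_spec(1, L = 4, family = "AR",
                                            sparse = TRUE, tau = 1))
  ds2 <- build_features(rec, ws, model_spec(1, L = 4, family = "AR"))
  expect_identical(ds1$X, ds2$X)
  expect_identical(ds1$dy, ds2$dy)
})

test_that("one-step prediction arithmetic and block-nulling equivalence", {
  m0 <- structure(list(theta = c(0, 0), spec = model_spec(1, L = 2),
                       blocks = list(a = 1:2)), class = "fitted_model")
  expect_identical(predict_one_step(m0, c(5, 3), y_t = 4)$y_next, 4)

  m1 <- structure(list(theta = 0.5, spec = model_spec(1, L = 1),
                       blocks = list(a = 1)), class = "fitted_model")
  expect_identical(predict_one_step(m1, 2)$dy, 1)
  expect_error(predict_one_step(m1, c(1, 2)), "dimension")

  # switched with c = [1], U = 1, a = [0.5], y(t-1) = 2 -> dy = 3
  m2 <- structure(list(theta = c(0.5, 1), spec = model_spec(1, L = 1,
                                                            family = "SL_AR"),
                       blocks = list(a = 1, c = 2)), class = "fitted_model")
  expect_identical(predict_one_step(m2, c(2, 1 * 2))$dy, 3)

  # a switched or bilinear model with c = 0 predicts like the linear model
  w <- quick_world(seed = 4, C = 1, L = 3, M = 2, family = "SL_ARX",
                   frequencies = 50, reps = 2)
  for (g in c("switched", "bilinear")) {
    sp <- model_spec(1, L = 3, M = 2, family = "SL_ARX", gating = g)
    ds <- build_features(w$rec, w$ws, sp)
    dsl <- build_features(w$rec, w$ws, model_spec(1, L = 3, M = 2,
                                                  family = "ARX"))
    th_lin <- c(1, -0.5, 0.2, 0.3, -0.1)
    th_sl <- c(th_lin[1:3], 0, 0, 0, th_lin[4:5])
    expect_equal(drop(ds$X %*% th_sl), drop(dsl$X %*% th_lin))
  }
})

test_that("rollout reproduces the simulator and collapses to one-step", {
  w <- quick_world(seed = 6, C = 1, L = 3, M = 2, family = "SL_ARX",
                   frequencies = c(10, 200), reps = 2, noise_sd = 0)
  u <- encode_input(w$sched, w$rec$T)
  U <- gating_signal(u, w$sched, "switched")
  th <- true_theta(w)
  model <- structure(list(theta = th, spec = w$spec,
                          blocks = list(a = 1:3, c = 4:6, b = 7:8),
                          sources = integer(0)),
                     class = "fitted_model")
  H <- 3000L
  n <- 2000L
  pred <- rollout(model, w$rec$signal[1, 1:H], u, U, n)
  expect_equal(pred, w$rec$signal[1, H + 1:n], tolerance = 1e-9)

  # k = 1 equals one-step prediction
  ds <- build_features(w$rec, w$ws, w$spec)
  i <- 40L
  s <- ds$t[i] + 1L
  one <- rollout(model, w$rec$signal[1, 1:s], u, U, 1L)
  expect_equal(one, ds$y_t[i] + predict_one_step(model, ds$X[i, ])$dy,
               tolerance = 1e-12)

  # zero model, zero input -> all-zero trajectory
  z <- rollout(model, rep(0, 10), numeric(30), numeric(30), 15L)
  expect_true(all(z == 0))
  expect_error(rollout(model, 1, u, U, 5), "history")
})

test_that("delay-time selection by auto mutual information", {
  set.seed(1)
  expect_identical(select_tau(rnorm(3000)), 1L)
  t <- 0:2999
  s <- sin(2 * pi * t / 20) + rnorm(3000, sd = 0.05)
  expect_true(select_tau(s) %in% 4:6)       # quarter of the 20 ms period
  expect_identical(select_tau(t / 3000 + sin(2 * pi * t / 5000)), 20L)
  expect_error(select_tau(rep(1, 1000)), "constant")
})
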