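# Minimal dataset wrapper so closed-form cases can bypass build_features.
toy_dataset <- function(X, dy, spec = model_spec(1, L = ncol(X),
                                                 family = "AR")) {
  structure(list(X = X, dy = dy, window = rep(1L, nrow(X)),
                 fold = rep(1L, nrow(X)), is_test = rep(FALSE, nrow(X)),
                 t = seq_len(nrow(X)), y_t = numeric(nrow(X)),
                 spec = spec, sources = integer(0),
                 blocks = list(a = seq_len(ncol(X))), n = nrow(X)),
            class = "regression_dataset")
}

test_that("ridge closed forms", {
  d <- toy_dataset(matrix(c(1, 2), 2, 1), c(2, 4))
  expect_equal(fit_ridge(d, lambda = 0)$theta, 2, tolerance = 1e-12)
  # (X'X + N lambda) theta = X'y: theta = 10 / (5 + 2 * 0.1)
  expect_equal(fit_ridge(d, lambda = 0.1)$theta, 10 / 5.2,
               tolerance = 1e-12)

  # noiseless geometric decay y(t+1) = 0.9 y(t); with features at t-1 the
  # increment is dy(t) = -0.1 * 0.9 * y(t-1), so a = -0.09
  y <- 0.9^(0:40)
  X <- matrix(y[1:39], ncol = 1)          # y(t-1)
  dy <- y[3:41] - y[2:40]                 # dy(t)
  expect_equal(fit_ridge(toy_dataset(X, dy), lambda = 0)$theta, -0.09,
               tolerance = 1e-9)
})

test_that("ridge matches the normal-equations oracle on random instances", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    p <- sample(1:15, 1)
    X <- matrix(rnorm(n * p), n, p)
    dy <- rnorm(n)
    lam <- runif(1, 0, 0.5)
    th <- fit_ridge(toy_dataset(X, dy), lambda = lam)$theta
    oracle <- solve(crossprod(X) + diag(n * lam, p), crossprod(X, dy))
    expect_equal(th, drop(oracle), tolerance = 1e-8)
  }
})

test_that("monotone shrinkage in lambda; min-norm fallback warns", {
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3)
  dy <- rnorm(20)
  d <- toy_dataset(X, dy)
  norms <- sapply(c(0, 0.01, 0.1, 1, 10), function(l)
    sqrt(sum(fit_ridge(d, lambda = l)$theta^2)))
  expect_true(all(diff(norms) <= 1e-12))

  Xs <- cbind(X[, 1], X[, 1])             # rank-deficient
  expect_warning(m <- fit_ridge(toy_dataset(Xs, dy), lambda = 0),
                 "minimum-norm")
  expect_equal(m$theta[1], m$theta[2], tolerance = 1e-8)
})

test_that("parameter recovery on synthetic switched-ARX data", {
  w <- quick_world(seed = 31, C = 2, L = 4, M = 3, family = "SL_ARX",
                   frequencies = c(10, 50, 200), reps = 4, noise_sd = 0.1)
  ds <- build_features(w$rec, w$ws, w$spec)
  m <- fit_ridge(ds, lambda = 1e-6, rows = "all")
  expect_lt(max(abs(m$theta - true_theta(w))), 0.05)
})

test_that("constrained fit freezes a and recovers b", {
  w <- quick_world(seed = 13, C = 1, L = 3, M = 2, family = "ARX",
                   frequencies = c(25, 100), reps = 4, noise_sd = 0.05)
  ds <- build_features(w$rec, w$ws, w$spec)
  a_true <- w$sys$a[, 1]
  m <- fit_constrained_stim(ds, a_true, lambda = 1e-8)
  expect_identical(m$theta[ds$blocks$a], a_true)
  expect_lt(max(abs(m$theta[ds$blocks$b] - w$sys$b[, 1])), 0.05)
  expect_error(fit_constrained_stim(ds, c(1, 2)), "length")

  # a_fixed = 0 reduces to an input-only regression
  m0 <- fit_constrained_stim(ds, rep(0, 3), lambda = 0.1)
  tr <- !ds$is_test
  Xb <- ds$X[tr, ds$blocks$b]
  oracle <- solve(crossprod(Xb) + diag(sum(tr) * 0.1, 2),
                  crossprod(Xb, ds$dy[tr]))
  expect_equal(m0$theta[ds$blocks$b], drop(oracle), tolerance = 1e-10)

  # M = 0: nothing to learn, frozen model returned unchanged
  dsa <- build_features(w$rec, w$ws, model_spec(1, L = 3, family = "AR"))
  mfroz <- fit_constrained_stim(dsa, a_true)
  expect_identical(mfroz$theta, a_true)
})

test_that("order grid search recovers a small planted (L, M)", {
  # planted L = 3, M = 2 searched on compact grids (same machinery as the
  # full-size grids, which are exercised in the acceptance suite)
  w <- quick_world(seed = 41, C = 1, L = 3, M = 2, family = "ARX",
                   frequencies = c(25, 100), reps = 6, noise_sd = 0.05)
  gs <- grid_search_orders(w$rec, w$ws, k = 1,
                           L_grid = c(0L, 1L, 3L, 6L),
                           M_grid = c(0L, 2L, 4L), lambda = 1e-4)
  expect_equal(unname(gs$mean_best), c(3L, 2L))
  expect_equal(unname(gs$median_best), c(3L, 2L))
  # default grids follow the published search
  expect_identical(eval(formals(grid_search_orders)$L_grid),
                   c(0L, 1L, seq(50L, 500L, 50L)))
  expect_identical(eval(formals(grid_search_orders)$M_grid),
                   c(0L, 100L, 200L, 300L))
  expect_error(grid_search_orders(w$rec, w$ws, L_grid = integer(0)),
               "empty")
})

test_that("white-noise target selects the smallest order by tie-break", {
  geom <- electrode_geometry(matrix(0, 1, 3))
  sched <- make_schedule(frequencies = 10, amplitudes = 0, reps = 8,
                         seed = 2)
  set.seed(2)
  rec <- recording(matrix(rnorm(30000), 1), geom, sched)
  ws <- extract_windows_and_folds(rec, seed = 2)
  gs <- grid_search_orders(rec, ws, L_grid = c(0L, 1L, 5L),
                           M_grid = c(0L, 2L), lambda = 0.1)
  # on a pure-noise target no order is significantly better, so the
  # median (signed-rank) criterion falls to the simplest by tie-break
  expect_lte(gs$median_best["L"], 1)
})

test_that("network lag refinement", {
  w <- quick_world(seed = 51, C = 3, L = 3, M = 2, P = 1,
                   family = "SL_VARX", frequencies = c(25, 100), reps = 6,
                   noise_sd = 0.1)
  # strong planted lag-1 coupling; light penalty so deep source lags do
  # not win by sharing the shrinkage of the true lag (see vignette)
  w$sys$d[, , ] <- 0
  w$sys$d[1, 2, 1] <- 0.4
  w$sys$d[1, 3, 1] <- -0.3
  rec <- simulate_recording(w$sys, w$sched, seed = 51)
  sel <- select_network_lags(rec, w$ws, w$spec,
                             P_grid = c(1L, 11L, 21L), lambda = 1e-3)
  expect_identical(sel$best_P, 1L)
  expect_true(all(diff(sel$table$mse) > 0))
  # default grid follows the printed 1..100-by-10 rule
  expect_identical(eval(formals(select_network_lags)$P_grid),
                   c(seq(1L, 91L, 10L), 100L))
  # no sources -> P = 0 with note
  sp0 <- model_spec(1, L = 3, M = 2, family = "ARX")
  sel0 <- select_network_lags(w$rec, w$ws, sp0)
  expect_identical(sel0$best_P, 0L)
  expect_match(sel0$note, "no network sources")
})
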