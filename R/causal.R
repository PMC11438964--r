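#' Bootstrap test of a direct stimulation effect
#'
#' Tests whether input lags causally improve one-step prediction for a
#' channel. The observed statistic is the held-out test MSE of the model
#' fitted on the original dataset. Each of `n_boot` null replicates
#' permutes the raw input series `u` across the in-window time samples,
#' rebuilds the input-lag features, refits and retests. The p-value uses
#' the add-one rule `p = (1 + #{null MSE <= observed}) / (1 + n_boot)` and
#' a direct effect is declared when `p < alpha`.
#'
#' @param rec a [recording].
#' @param ws a [extract_windows_and_folds] result.
#' @param spec a [model_spec] with an input block (`M > 0`).
#' @param n_boot null replicates (default 100).
#' @param alpha significance level.
#' @param lambda ridge penalty.
#' @param seed integer seed for the permutations.
#' @param events optional corrected event table.
#' @return An object of class `causal_test`: `observed_mse`, `null_mse`
#'   (length `n_boot`), `p`, `reject`, `n_boot`, `seed`, `degenerate`.
#' @export
bootstrap_input_test <- function(rec, ws, spec, n_boot = 100L,
                                 alpha = 0.05, lambda = 0.1, seed = 1L,
                                 events = NULL) {
  if (!family_blocks(spec$family)$has_b || spec$M == 0L)
    stopf("spec has no input block (M = 0)")
  ev <- events %||% rec$schedule$events
  ds <- build_features(rec, ws, spec, events = ev)
  obs <- evaluate_model(fit_ridge(ds, lambda), ds)$mse
  u <- encode_input(ev, rec$T)
  if (all(u == 0))
    return(causal_test(obs, rep(obs, n_boot), n_boot, seed, alpha,
                       degenerate = TRUE))
  widx <- in_window_samples(ws, rec$T)
  s <- ds$t + 1L
  bil <- ds$spec$gating == "bilinear"
  set.seed(child_seed(seed, "boot-input"))
  null_mse <- vapply(seq_len(n_boot), function(r) {
    up <- u
    up[widx] <- u[sample(widx)]
    X <- ds$X
    for (j in seq_len(spec$M)) X[, ds$blocks$b[j]] <- up[s - j]
    if (bil) {
      a_lags <- if (spec$sparse) spec$tau * seq_len(spec$L)
                else seq_len(spec$L)
      for (j in seq_len(spec$L))
        X[, ds$blocks$c[j]] <- up[s] * rec$signal[spec$k, s - a_lags[j]]
    }
    refit_mse(X, ds, lambda)
  }, numeric(1))
  causal_test(obs, null_mse, n_boot, seed, alpha)
}

#' Bootstrap test of network-mediated causal effects
#'
#' Same resampling logic as [bootstrap_input_test], but each null replicate
#' permutes the network-history feature rows (the stacked lagged values of
#' all other channels) jointly across time samples, leaving the channel's
#' own history and the input untouched.
#'
#' @inheritParams bootstrap_input_test
#' @param spec a [model_spec] of a network family with `P > 0`.
#' @return A `causal_test` object.
#' @export
bootstrap_network_test <- function(rec, ws, spec, n_boot = 100L,
                                   alpha = 0.05, lambda = 0.1, seed = 1L,
                                   events = NULL) {
  if (rec$C < 2L) stopf("network test needs more than one channel")
  if (!family_blocks(spec$family)$has_d || spec$P == 0L)
    stopf("spec has no network block (P = 0)")
  ds <- build_features(rec, ws, spec, events = events)
  if (length(ds$sources) == 0L) stopf("empty network source set")
  obs <- evaluate_model(fit_ridge(ds, lambda), ds)$mse
  dcols <- unlist(ds$blocks$d)
  set.seed(child_seed(seed, "boot-network"))
  null_mse <- vapply(seq_len(n_boot), function(r) {
    X <- ds$X
    X[, dcols] <- X[sample(ds$n), dcols]
    refit_mse(X, ds, lambda)
  }, numeric(1))
  causal_test(obs, null_mse, n_boot, seed, alpha)
}

refit_mse <- function(X, ds, lambda) {
  tr <- !ds$is_test
  th <- ridge_solve(crossprod(X[tr, , drop = FALSE]),
                    crossprod(X[tr, , drop = FALSE], ds$dy[tr]),
                    sum(tr) * lambda)
  mean((ds$dy[!tr] - drop(X[!tr, , drop = FALSE] %*% th))^2)
}

causal_test <- function(obs, null_mse, n_boot, seed, alpha,
                        degenerate = FALSE) {
  p <- (1 + sum(null_mse <= obs)) / (1 + length(null_mse))
  structure(
    list(observed_mse = obs, null_mse = null_mse, p = p,
         reject = !degenerate && p < alpha, alpha = alpha,
         n_boot = length(null_mse), seed = as.integer(seed),
         degenerate = degenerate),
    class = "causal_test")
}

#' @export
print.causal_test <- function(x, ...) {
  cat(sprintf("<causal_test> observed MSE %.4g, p = %.4g (%s)%s\n",
              x$observed_mse, x$p,
              if (x$reject) "causal effect" else "no effect detected",
              if (x$degenerate) " [degenerate input]" else ""))
  invisible(x)
}

# Union of 0-based sample indices covered by windows, as R indices.
in_window_samples <- function(ws, T_total) {
  idx <- unlist(lapply(seq_len(nrow(ws$windows)), function(w)
    (ws$windows$start[w]:(ws$windows$end[w] - 1L)) + 1L))
  unique(idx[idx >= 1L & idx <= T_total])
}

#' Indirect test of linearity across stimulation regimes
#'
#' Splits the channel's samples into three sub-datasets: (1) STIM OFF,
#' (2) one half of the STIM ON windows, (3) the other half. An AR model on
#' dataset 1 yields autoregressive weights `a1`. Dataset 2 trains a full
#' ARX model `{a2, b2}` and a constrained one `{a1, b3}` (autoregressive
#' block frozen, input block re-learned; see [fit_constrained_stim]). Both
#' are then scored on dataset 3. If the dynamics are linear, freezing `a`
#' costs nothing; if switching is present, the fully STIM-ON-trained model
#' is significantly better (one-sided signed-rank across windows).
#'
#' @param rec,ws,events as in [bootstrap_input_test].
#' @param spec an ARX-family [model_spec] (`L`, `M` set; `family = "ARX"`).
#' @param lambda ridge penalty.
#' @param alpha significance level.
#' @param seed seed for the ON-window split.
#' @return list with `mse_rs` (frozen-a model), `mse_stim` (full ON model),
#'   `delta = mse_rs - mse_stim`, `p`, `decision` (`"nonlinear"` or
#'   `"linear"`), and per-window errors.
#' @export
linearity_test <- function(rec, ws, spec, lambda = 0.1, alpha = 0.05,
                           seed = 1L, events = NULL) {
  ev <- events %||% rec$schedule$events
  ds <- build_features(rec, ws, spec, events = ev)
  on_mask <- stim_on_mask(ev, rec$T)
  row_on <- on_mask[ds$t + 2L]          # regime of the target sample t + 1
  if (!any(row_on) || !any(!row_on)) stopf("need both STIM ON and OFF data")
  on_windows <- sort(unique(ds$window[row_on]))
  if (length(on_windows) < 2L) stopf("need at least two STIM ON windows")
  set.seed(child_seed(seed, "linearity-split"))
  half <- sample(on_windows, ceiling(length(on_windows) / 2))
  ds2_rows <- row_on & ds$window %in% half
  ds3_rows <- row_on & !ds$window %in% half

  acols <- ds$blocks$a
  # dataset 1: STIM OFF -> a1 (AR fit on the a columns only)
  Xoff <- ds$X[!row_on, acols, drop = FALSE]
  a1 <- drop(ridge_solve(crossprod(Xoff), crossprod(Xoff, ds$dy[!row_on]),
                         nrow(Xoff) * lambda))
  # dataset 2: STIM ON -> full ARX {a2, b2} and constrained {a1, b3}
  full <- fit_ridge(ds, lambda, rows = ds2_rows)
  constr <- fit_constrained_stim(ds, a1, lambda, rows = ds2_rows)
  # dataset 3: held-out STIM ON evaluation
  e_stim <- (ds$dy[ds3_rows] -
               drop(ds$X[ds3_rows, , drop = FALSE] %*% full$theta))^2
  e_rs <- (ds$dy[ds3_rows] -
             drop(ds$X[ds3_rows, , drop = FALSE] %*% constr$theta))^2
  w3 <- ds$window[ds3_rows]
  wm_stim <- tapply(e_stim, w3, mean)
  wm_rs <- tapply(e_rs, w3, mean)
  p <- if (length(wm_stim) >= 6L) {
    suppressWarnings(stats::wilcox.test(wm_stim, wm_rs, paired = TRUE,
                                        alternative = "less")$p.value)
  } else {
    stats::t.test(wm_stim, wm_rs, paired = TRUE,
                  alternative = "less")$p.value
  }
  list(mse_rs = mean(e_rs), mse_stim = mean(e_stim),
       delta = mean(e_rs) - mean(e_stim), p = p,
       decision = if (!is.na(p) && p < alpha) "nonlinear" else "linear",
       window_mse_stim = wm_stim, window_mse_rs = wm_rs,
       a1 = a1, model_stim = full, model_rs = constr)
}
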