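# Generalization experiments: training on subsets of stimulation
# frequencies, and transferring models across recording sessions.

#' Frequency-subset generalization experiment
#'
#' Splits the windows by stimulation condition (pulse-train frequency, with
#' `0` denoting stimulation-free STIM OFF windows), then for every
#' non-empty subset of the six conditions trains a model on the training
#' folds of that subset's windows and evaluates it on a fixed held-out set:
#' the test folds of all windows of all conditions. Reports the NMSE per
#' subset and its mean as a function of the subset size `k`. A
#' frequency-independent (switched) ground truth yields a flat curve; a
#' bilinear one improves as more frequencies are seen in training.
#'
#' @param rec a [recording].
#' @param ws a [extract_windows_and_folds] result containing windows for
#'   all conditions in `conditions` (use `n_off_windows > 0` to include
#'   the 0 Hz condition).
#' @param spec the [model_spec] to train (typically `SL_ARX`).
#' @param conditions the condition set; default `{0, 10, 25, 50, 100, 200}`.
#' @param lambda ridge penalty.
#' @param events optional corrected event table.
#' @return list with `table` (one row per subset: `k`, `subset`, `nmse`)
#'   and `summary` (mean NMSE per `k`).
#' @export
frequency_subset_experiment <- function(rec, ws, spec,
                                        conditions = c(0, 10, 25, 50,
                                                       100, 200),
                                        lambda = 0.1, events = NULL) {
  wcond <- ws$windows$freq_hz
  missing <- setdiff(conditions, unique(wcond))
  if (length(missing) > 0L)
    stopf("missing windows for condition(s): %s",
          paste(missing, collapse = ", "))
  ds <- build_features(rec, ws, spec, events = events)
  cond_of_row <- wcond[ds$window]
  tr <- !ds$is_test
  te <- ds$is_test
  dyte <- ds$dy[te]
  Xte <- ds$X[te, , drop = FALSE]
  # per-condition training Gram blocks, summed per subset
  G_c <- list(); g_c <- list(); n_c <- list()
  for (cc in conditions) {
    sel <- tr & cond_of_row == cc
    Xc <- ds$X[sel, , drop = FALSE]
    G_c[[as.character(cc)]] <- crossprod(Xc)
    g_c[[as.character(cc)]] <- crossprod(Xc, ds$dy[sel])
    n_c[[as.character(cc)]] <- sum(sel)
  }
  rows <- list()
  nc <- length(conditions)
  for (k in seq_len(nc)) {
    subs <- utils::combn(conditions, k, simplify = FALSE)
    for (sub in subs) {
      key <- as.character(sub)
      G <- Reduce(`+`, G_c[key]); g <- Reduce(`+`, g_c[key])
      N <- sum(unlist(n_c[key]))
      th <- ridge_solve(G, g, N * lambda)
      nm <- nmse(drop(Xte %*% th), dyte)
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, subset = paste(sub, collapse = "+"), nmse = nm)
    }
  }
  tab <- do.call(rbind, rows)
  list(table = tab,
       summary = stats::aggregate(nmse ~ k, data = tab, FUN = mean))
}

#' Cross-session generalization experiment
#'
#' Fits the same (STIM OFF) channel model on session A only, session B
#' only, and the pooled sessions, then evaluates all three on the held-out
#' folds of session A. When both sessions realize the same dynamics the
#' pooled model matches or beats the A-only model; a perturbed session B
#' drags the pooled model away from A's law.
#'
#' @param recA,recB two [recording]s of the same channel layout.
#' @param wsA,wsB their window sets.
#' @param spec the channel [model_spec]; per the stimulation-site rationale
#'   an AR family fitted on STIM OFF samples (`stim_off_only = TRUE`).
#' @param stim_off_only restrict all fitting/testing to samples whose
#'   target lies outside stimulation spans.
#' @param lambda ridge penalty.
#' @return list with `mse` (named: `A`, `B`, `AB`), `window_mse`
#'   (windows x models), `comparison` (a [median_best] result).
#' @export
session_experiment <- function(recA, recB, wsA, wsB, spec,
                               stim_off_only = TRUE, lambda = 0.1) {
  dsA <- build_features(recA, wsA, spec)
  dsB <- build_features(recB, wsB, spec)
  offA <- if (stim_off_only)
    !stim_on_mask(recA$schedule$events, recA$T)[dsA$t + 2L]
  else rep(TRUE, dsA$n)
  offB <- if (stim_off_only)
    !stim_on_mask(recB$schedule$events, recB$T)[dsB$t + 2L]
  else rep(TRUE, dsB$n)
  trA <- offA & !dsA$is_test
  teA <- offA & dsA$is_test
  trB <- offB & !dsB$is_test
  if (sum(teA) == 0L || sum(trA) == 0L || sum(trB) == 0L)
    stopf("a session lacks training or held-out data")
  fit_rows <- function(X, dy) {
    drop(ridge_solve(crossprod(X), crossprod(X, dy), nrow(X) * lambda))
  }
  thA <- fit_rows(dsA$X[trA, , drop = FALSE], dsA$dy[trA])
  thB <- fit_rows(dsB$X[trB, , drop = FALSE], dsB$dy[trB])
  thAB <- fit_rows(rbind(dsA$X[trA, , drop = FALSE],
                         dsB$X[trB, , drop = FALSE]),
                   c(dsA$dy[trA], dsB$dy[trB]))
  Xte <- dsA$X[teA, , drop = FALSE]; dyte <- dsA$dy[teA]
  wte <- dsA$window[teA]
  errs <- sapply(list(A = thA, B = thB, AB = thAB), function(th)
    (dyte - drop(Xte %*% th))^2)
  wm <- apply(errs, 2L, function(e) tapply(e, wte, mean))
  np <- rep(length(thA), 3L)
  cmp <- median_best(wm, n_params = np)
  list(mse = colMeans(errs), window_mse = wm, comparison = cmp)
}
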