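#' Preprocess a recording
#'
#' Minimal pipeline applied per channel: zero-phase Butterworth notch
#' filters at the power-line harmonics, first-order polynomial detrend, then
#' z-scoring over the whole channel. Constant (zero-variance) channels are
#' flagged and left un-scaled with a warning.
#'
#' @param rec a [recording] sampled at 1000 Hz.
#' @param notch_freqs harmonics to remove (Hz).
#' @param notch_halfwidth half-width of each stop band (Hz).
#' @param order overall Butterworth order of each notch.
#' @return The preprocessed [recording]; flagged channel indices are in
#'   `attr(, "constant_channels")`.
#' @export
preprocess_signal <- function(rec, notch_freqs = c(60, 120, 180),
                              notch_halfwidth = 1, order = 4L) {
  if (rec$fs != 1000) stopf("expected fs = 1000 Hz")
  y <- rec$signal
  tt <- seq_len(ncol(y))
  flagged <- integer(0)
  filters <- lapply(notch_freqs, function(f0)
    butter_bandstop(f0 - notch_halfwidth, f0 + notch_halfwidth, rec$fs, order))
  for (k in seq_len(nrow(y))) {
    x <- y[k, ]
    if (stats::sd(x) < 1e-12) {        # constant before any filtering
      flagged <- c(flagged, k)
      warnf("channel %d is constant; z-score skipped", k)
      next
    }
    for (fl in filters) x <- filtfilt2(x, fl$b, fl$a)
    x <- stats::lm.fit(cbind(1, tt), x)$residuals
    y[k, ] <- x / stats::sd(x)
  }
  out <- recording(y, rec$geometry, rec$schedule, rec$session_id,
                   preprocessed = TRUE)
  attr(out, "constant_channels") <- flagged
  out
}

#' Correct reported stimulation onsets against the anode response
#'
#' Logged delivery times can lag the true delivery. For each event the onset
#' is moved to the first sample within `search_halfwidth_ms` of the reported
#' onset where the absolute one-step difference of the anode channel exceeds
#' `threshold_mult` times the standard deviation of that difference over the
#' event's pre-stimulation baseline. Events with no super-threshold sample
#' keep their reported onset and are flagged.
#'
#' @param rec a [recording] (anode channel from its geometry).
#' @param events event table to correct; defaults to the recording's own.
#' @param search_halfwidth_ms search half-width around the reported onset.
#' @param threshold_mult threshold in baseline standard deviations.
#' @param latency_samples intrinsic input-to-output latency of the model
#'   convention (the input at `t` first moves the signal at `t + 2`:
#'   one sample because features use `u(t - 1)`, one because the increment
#'   updates `y(t + 1)`); subtracted from the detected response time.
#' @return list with `events` (corrected table), `delay_ms` (per-event
#'   correction, NA when flagged) and `flagged` (logical vector).
#' @export
correct_onsets <- function(rec, events = NULL,
                           search_halfwidth_ms = 50,
                           threshold_mult = 5,
                           latency_samples = 2L) {
  ev <- events %||% rec$schedule$events
  anode <- rec$geometry$anode_index
  if (is.null(anode) || anode < 1L || anode > rec$C)
    stopf("anode channel unknown")
  ya <- rec$signal[anode, ]
  dy <- c(0, diff(ya))
  hw <- as.integer(search_halfwidth_ms)
  delays <- rep(NA_real_, nrow(ev))
  flagged <- logical(nrow(ev))
  new_onset <- ev$onset
  for (i in seq_len(nrow(ev))) {
    t0 <- ev$onset[i]
    base_idx <- max(2L, t0 - 500L):max(2L, t0 - hw - 1L) + 1L
    sd_base <- stats::sd(dy[base_idx])
    search <- (max(1L, t0 - hw):min(rec$T - 1L, t0 + hw)) + 1L
    if (!is.finite(sd_base) || sd_base < 1e-12) {
      flagged[i] <- TRUE
      next
    }
    hit <- which(abs(dy[search]) > threshold_mult * sd_base)
    if (length(hit) == 0L) {
      flagged[i] <- TRUE
    } else {
      t_star <- search[hit[1L]] - 1L - latency_samples  # 0-based samples
      delays[i] <- t_star - t0
      new_onset[i] <- t_star
    }
  }
  ev$onset <- as.integer(new_onset)
  list(events = ev, delay_ms = delays, flagged = flagged)
}

#' Extract per-event analysis windows and cross-validation folds
#'
#' Each stimulation delivery yields one 1500 ms window: 500 ms pre-stim,
#' 500 ms stim, 500 ms post-stim for pulse trains, and 750 ms pre / 750 ms
#' post for single pulses. Every window is split into five contiguous
#' 300 ms folds; one fold per window, drawn by `seed`, is held out for
#' testing and the other four are used for training. Windows that would
#' cross the recording edges are skipped with a warning.
#'
#' @param rec a [recording].
#' @param events event table (defaults to the recording's schedule; pass the
#'   output of [correct_onsets] to use corrected onsets).
#' @param seed integer seed for the held-out fold draw.
#' @param n_off_windows additionally extract up to this many 1500 ms
#'   stimulation-free windows (condition labeled `freq_hz = 0`) from gaps
#'   where no stimulation occurs; 0 by default.
#' @return An object of class `window_set`: data.frame `windows` with
#'   columns `start`, `end` (half-open sample span), `freq_hz`, `amp_ma`,
#'   `event`, `test_fold`, plus `fold_len = 300` and `n_folds = 5`.
#' @export
extract_windows_and_folds <- function(rec, events = NULL, seed = 1L,
                                      n_off_windows = 0L) {
  ev <- events %||% rec$schedule$events
  rows <- vector("list", nrow(ev))
  skipped <- 0L
  for (i in seq_len(nrow(ev))) {
    t0 <- ev$onset[i]
    if (ev$freq_hz[i] == -1) {
      start <- t0 - 750L; end <- t0 + 750L
    } else {
      start <- t0 - 500L; end <- t0 + 1000L
    }
    if (start < 0L || end > rec$T) {
      skipped <- skipped + 1L
      next
    }
    rows[[i]] <- data.frame(start = start, end = end,
                            freq_hz = ev$freq_hz[i], amp_ma = ev$amp_ma[i],
                            event = i)
  }
  win <- do.call(rbind, rows)
  if (skipped > 0L)
    warnf("%d window(s) too close to the recording edges were skipped",
          skipped)
  if (n_off_windows > 0L) {
    off <- find_off_windows(rec, ev, n_off_windows)
    win <- rbind(win, off)
  }
  if (is.null(win) || nrow(win) == 0L) stopf("no extractable windows")
  set.seed(child_seed(seed, "folds"))
  win$test_fold <- sample.int(5L, nrow(win), replace = TRUE)
  rownames(win) <- NULL
  structure(list(windows = win, fold_len = 300L, n_folds = 5L,
                 seed = as.integer(seed)),
            class = "window_set")
}

# Stimulation-free 1500 ms windows ("0 Hz" condition) from schedule gaps.
find_off_windows <- function(rec, ev, n_max, margin = 250L) {
  on <- stim_on_mask(ev, rec$T)
  # also keep clear of the per-event analysis windows
  for (i in seq_len(nrow(ev))) {
    lo <- max(1L, ev$onset[i] - 750L + 1L)
    hi <- min(rec$T, ev$onset[i] + 1000L + 1L)
    on[lo:hi] <- TRUE
  }
  free <- !on
  rows <- list()
  s <- 1L
  while (length(rows) < n_max && s + 1500L + 2L * margin <= rec$T) {
    span <- s:(s + 1500L + 2L * margin - 1L)
    if (all(free[span])) {
      start <- s + margin - 1L                 # 0-based
      rows[[length(rows) + 1L]] <- data.frame(
        start = start, end = start + 1500L,
        freq_hz = 0, amp_ma = 0, event = NA_integer_)
      s <- s + 1500L + 2L * margin
    } else {
      s <- s + 100L
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

# Fold index (1..5) of an absolute 0-based sample within window w.
fold_of_sample <- function(ws, w, t) {
  1L + (t - ws$windows$start[w]) %/% ws$fold_len
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows x 5 folds of %d ms\n",
              nrow(x$windows), x$fold_len))
  invisible(x)
}
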