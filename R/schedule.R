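#' Allowed pulse-train frequencies (Hz)
#'
#' `-1` encodes a single pulse. Exported as a constant so schedules, input
#' encoding and experiment code agree on the factorial design.
#' @export
STIM_FREQUENCIES <- c(-1, 10, 25, 50, 100, 200)

#' Stimulation schedule
#'
#' Build a factorial stimulation schedule: every combination of frequency and
#' amplitude is delivered `reps` times in a seed-shuffled order, as
#' fixed-duration biphasic pulse trains separated by stimulation-free gaps.
#'
#' Time is measured in samples at 1000 Hz (1 sample = 1 ms), 0-based.
#'
#' @param frequencies pulse-train frequencies in Hz; `-1` means single pulse.
#'   Must be a subset of [STIM_FREQUENCIES].
#' @param amplitudes stimulation amplitudes in mA. Default: the three levels
#'   `A_safe`, `A_safe - 0.25`, `A_safe - 0.5`.
#' @param reps deliveries per (frequency, amplitude) cell (>= 1).
#' @param gap_ms stimulation-free gap between consecutive deliveries
#'   (>= 1000 ms so 1500 ms analysis windows never overlap).
#' @param A_safe subject-specific maximum safe amplitude (mA).
#' @param start_ms onset of the first delivery (>= 1000 ms so the first
#'   pre-stimulation segment exists).
#' @param duration_ms pulse-train duration; the experimental design fixes
#'   this at 500 ms.
#' @param seed integer seed controlling the delivery order.
#' @return An object of class `stim_schedule`: a list with `events` (a
#'   data.frame with columns `onset`, `duration_ms`, `freq_hz`, `amp_ma`),
#'   `A_safe` and `gap_ms`.
#' @export
make_schedule <- function(frequencies = STIM_FREQUENCIES,
                          amplitudes = NULL,
                          reps = 20L,
                          gap_ms = 1500,
                          A_safe = 2.0,
                          start_ms = 2000,
                          duration_ms = 500,
                          seed = 1L) {
  if (reps < 1L) stopf("reps must be >= 1")
  if (gap_ms < 1000) stopf("gap_ms must be >= 1000 so windows never overlap")
  if (!all(frequencies %in% STIM_FREQUENCIES))
    stopf("frequencies must be a subset of {%s}",
          paste(STIM_FREQUENCIES, collapse = ", "))
  if (is.null(amplitudes)) amplitudes <- A_safe - c(0, 0.25, 0.5)
  cells <- expand.grid(freq_hz = frequencies, amp_ma = amplitudes,
                       rep = seq_len(reps), KEEP.OUT.ATTRS = FALSE)
  set.seed(child_seed(seed, "schedule"))
  ord <- sample.int(nrow(cells))
  cells <- cells[ord, , drop = FALSE]
  n <- nrow(cells)
  onsets <- start_ms + (seq_len(n) - 1L) * (duration_ms + gap_ms)
  ev <- data.frame(onset = as.integer(onsets),
                   duration_ms = as.integer(duration_ms),
                   freq_hz = as.numeric(cells$freq_hz),
                   amp_ma = as.numeric(cells$amp_ma))
  if (any(diff(ev$onset) < duration_ms + gap_ms)) stopf("overlapping events")
  structure(list(events = ev, A_safe = A_safe, gap_ms = gap_ms,
                 duration_ms = duration_ms, seed = as.integer(seed)),
            class = "stim_schedule")
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf("<stim_schedule> %d events, %d frequencies x %d amplitudes\n",
              nrow(x$events), length(unique(x$events$freq_hz)),
              length(unique(x$events$amp_ma))))
  invisible(x)
}

# Total recording length (samples) needed to hold a schedule plus trailing
# room for the post-stimulation window segment.
schedule_span <- function(schedule, tail_ms = 2000) {
  ev <- schedule$events
  max(ev$onset + ev$duration_ms) + tail_ms
}
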