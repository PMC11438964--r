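#' Simulate a stimulation-evoked multichannel recording
#'
#' Runs the ground-truth system forward at 1000 Hz:
#' `y_k(t+1) = y_k(t) + dy_k(t) + e_k(t)` with `dy_k(t)` given by the
#' one-step model under the system's own gating mode, the pulse-encoded
#' input from [encode_input], and i.i.d. Gaussian innovations of standard
#' deviation `noise_sd`.
#'
#' @param system a [sample_ground_truth_system] result.
#' @param schedule a [make_schedule] result.
#' @param duration_samples total length `T`; defaults to the schedule span
#'   plus trailing room.
#' @param init optional `C x max_lag` matrix of initial values (default 0).
#' @param seed integer seed for the innovations.
#' @return An object of class `recording`: `signal` (`C x T`), `fs`,
#'   `geometry`, `schedule`, `session_id`, `preprocessed` flag.
#' @export
simulate_recording <- function(system, schedule,
                               duration_samples = NULL,
                               init = NULL, seed = 1L,
                               session_id = "synthetic") {
  C <- system$C; L <- system$L; M <- system$M; P <- system$P
  if (max(companion_radius_by_channel(system)) > 1)
    stopf("refusing to simulate an unstable system")
  T_total <- as.integer(duration_samples %||% schedule_span(schedule))
  if (T_total < schedule_span(schedule, tail_ms = 0))
    stopf("duration does not cover the schedule")
  u <- encode_input(schedule, T_total)
  U <- gating_signal(u, schedule, system$gating)

  maxlag <- max(L, M, P, 1L)
  y <- matrix(0, nrow = C, ncol = T_total)
  if (!is.null(init)) {
    init <- as.matrix(init)
    y[, seq_len(ncol(init))] <- init
  }
  set.seed(child_seed(seed, "simulate"))
  eps <- if (system$noise_sd > 0)
    matrix(stats::rnorm(C * T_total, sd = system$noise_sd), nrow = C)
  else matrix(0, nrow = C, ncol = T_total)

  a <- system$a; b <- system$b; cb <- system$c; d <- system$d
  has_net <- P > 0L && any(d != 0)
  Dj <- if (has_net) lapply(seq_len(P), function(j) d[, , j]) else NULL
  for (s in seq(maxlag + 1L, T_total - 1L)) {
    dy <- numeric(C)
    if (L > 0L) {
      hist_a <- y[, s - seq_len(L), drop = FALSE]     # C x L
      coef <- a + U[s] * cb
      dy <- dy + rowSums(hist_a * t(coef))
    }
    if (M > 0L) {
      ulags <- u[s - seq_len(M)]
      dy <- dy + as.numeric(crossprod(b, ulags))
    }
    if (has_net) {
      for (j in seq_len(P)) dy <- dy + Dj[[j]] %*% y[, s - j]
    }
    y[, s + 1L] <- y[, s] + dy + eps[, s]
  }
  recording(y, geometry = system$geometry, schedule = schedule,
            session_id = session_id)
}

companion_radius_by_channel <- function(system) {
  vapply(seq_len(system$C), function(k) {
    max(companion_radius(system$a[, k]),
        companion_radius(system$a[, k] + system$c[, k]))
  }, numeric(1))
}

#' Recording container
#'
#' @param signal `C x T` numeric matrix, one row per channel, sampled at
#'   1000 Hz (1 sample = 1 ms).
#' @param geometry an [electrode_geometry].
#' @param schedule a [make_schedule] result (the event table drives input
#'   encoding and window extraction).
#' @param session_id free-form session label.
#' @return An object of class `recording`.
#' @export
recording <- function(signal, geometry, schedule,
                      session_id = "session", preprocessed = FALSE) {
  signal <- as.matrix(signal)
  if (nrow(signal) != geometry$n_channels)
    stopf("signal has %d rows but geometry has %d channels",
          nrow(signal), geometry$n_channels)
  if (anyNA(signal)) stopf("signal contains NAs")
  structure(
    list(signal = signal, fs = 1000, geometry = geometry,
         schedule = schedule, session_id = session_id,
         C = nrow(signal), T = ncol(signal),
         preprocessed = isTRUE(preprocessed)),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d channels x %d samples (%.1f s), %d events%s\n",
    x$C, x$T, x$T / x$fs, nrow(x$schedule$events),
    if (x$preprocessed) ", preprocessed" else ""))
  invisible(x)
}
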