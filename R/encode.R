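#' Encode a stimulation schedule as an input time series
#'
#' Builds the scalar input series `u(t)` from the event table: a pulse train
#' of frequency `f` (Hz) and amplitude `a` (mA) starting at sample `t_k` sets
#' `u(t_k + dt) = a` for every `dt` in `[0, duration]` that is an integer
#' multiple of `1000 / f`, and `u = 0` elsewhere. A single-pulse event
#' (`freq_hz = -1`) contributes exactly one nonzero sample at its onset.
#'
#' @param events a `stim_schedule` or its `events` data.frame.
#' @param T_total length of the series in samples.
#' @return numeric vector of length `T_total` (0-based time: `u[t + 1]` is
#'   the input at sample `t`).
#' @export
encode_input <- function(events, T_total) {
  ev <- if (inherits(events, "stim_schedule")) events$events else events
  u <- numeric(T_total)
  if (nrow(ev) == 0L) return(u)
  if (!all(ev$freq_hz %in% STIM_FREQUENCIES))
    stopf("frequency not in allowed set {%s}",
          paste(STIM_FREQUENCIES, collapse = ", "))
  if (any(ev$onset < 0L) || any(ev$onset >= T_total))
    stopf("event onset outside [0, T)")
  for (i in seq_len(nrow(ev))) {
    t_k <- ev$onset[i]; f <- ev$freq_hz[i]; a <- ev$amp_ma[i]
    if (f == -1) {
      u[t_k + 1L] <- a
      next
    }
    period <- 1000 / f
    dts <- round(period * (0:floor(ev$duration_ms[i] / period)))
    idx <- t_k + dts + 1L
    u[idx[idx <= T_total]] <- a
  }
  u
}

#' Gating series for the switching / bilinear model variants
#'
#' Computes the modulating series `U(t)` that multiplies the autoregressive
#' history in the interaction term of the model:
#' * `"switched"` — `U = 1` on every stimulation span `[t_k, t_k + duration]`
#'   (inclusive), else 0;
#' * `"amplitude"` — amplitude-weighted switched-linear: `U = a` on the same
#'   spans;
#' * `"bilinear"` — `U` equals the pulse-encoded input `u` elementwise;
#' * `"none"` — identically zero (purely linear families).
#'
#' @param u input series from [encode_input] (used by mode `"bilinear"`).
#' @param events a `stim_schedule` or its `events` data.frame.
#' @param mode one of `"none"`, `"switched"`, `"amplitude"`, `"bilinear"`.
#' @return numeric vector the same length as `u`.
#' @export
gating_signal <- function(u, events, mode) {
  mode <- match.arg(mode, c("none", "switched", "amplitude", "bilinear"))
  if (mode == "bilinear") return(u)
  U <- numeric(length(u))
  if (mode == "none") return(U)
  ev <- if (inherits(events, "stim_schedule")) events$events else events
  for (i in seq_len(nrow(ev))) {
    if (ev$freq_hz[i] == -1) {
      span <- ev$onset[i] + 1L          # single pulse: gate only its sample
    } else {
      span <- (ev$onset[i]:(ev$onset[i] + ev$duration_ms[i])) + 1L
    }
    span <- span[span >= 1L & span <= length(u)]
    U[span] <- if (mode == "switched") 1 else ev$amp_ma[i]
  }
  U
}

# STIM ON indicator: samples inside any [t_k, t_k + duration] span.
stim_on_mask <- function(events, T_total) {
  gating_signal(numeric(T_total), events, "switched") > 0
}
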