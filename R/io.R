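# Plain-text container for recordings and ground-truth sidecars.
#
# A recording is stored as a directory of CSV files plus a JSON metadata
# file: signal.csv (T rows x C channel columns), coords.csv (channel, x, y,
# z), events.csv (onset_sample, duration_ms, freq_hz with -1 for single
# pulse, amp_ma), meta.json (fs, anode_index, session_id, A_safe, gap_ms).
# Floats are written with 17 significant digits so a round trip is exact
# to well below 1e-12.

fmt_num <- function(x) sprintf("%.17g", x)

write_num_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, function(col) {
    if (is.double(col)) fmt_num(col) else col
  }))
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write a recording to a plain-text container directory
#'
#' @param rec a [recording].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create container directory %s", path)
  sig <- as.data.frame(t(rec$signal))
  names(sig) <- paste0("ch", seq_len(rec$C))
  write_num_csv(sig, file.path(path, "signal.csv"))
  co <- as.data.frame(rec$geometry$coords)
  names(co) <- c("x", "y", "z")
  co <- cbind(channel = seq_len(rec$C), co)
  write_num_csv(co, file.path(path, "coords.csv"))
  ev <- rec$schedule$events
  write_num_csv(
    data.frame(onset_sample = ev$onset, duration_ms = ev$duration_ms,
               freq_hz = ev$freq_hz, amp_ma = ev$amp_ma),
    file.path(path, "events.csv"))
  meta <- list(fs = rec$fs, anode_index = rec$geometry$anode_index,
               session_id = rec$session_id,
               A_safe = rec$schedule$A_safe,
               gap_ms = rec$schedule$gap_ms,
               duration_ms = rec$schedule$duration_ms,
               preprocessed = rec$preprocessed)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording container directory
#'
#' @param path directory written by [write_recording].
#' @return A [recording].
#' @export
read_recording <- function(path) {
  need <- c("signal.csv", "coords.csv", "events.csv", "meta.json")
  miss <- need[!file.exists(file.path(path, need))]
  if (length(miss) > 0L)
    stopf("container %s is missing: %s", path, paste(miss, collapse = ", "))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  sig <- utils::read.csv(file.path(path, "signal.csv"))
  co <- utils::read.csv(file.path(path, "coords.csv"))
  ev <- utils::read.csv(file.path(path, "events.csv"))
  geom <- electrode_geometry(as.matrix(co[, c("x", "y", "z")]),
                             anode_index = meta$anode_index)
  sched <- structure(
    list(events = data.frame(onset = as.integer(ev$onset_sample),
                             duration_ms = as.integer(ev$duration_ms),
                             freq_hz = ev$freq_hz, amp_ma = ev$amp_ma),
         A_safe = meta$A_safe, gap_ms = meta$gap_ms,
         duration_ms = meta$duration_ms, seed = NA_integer_),
    class = "stim_schedule")
  recording(t(as.matrix(sig)), geom, sched, meta$session_id,
            preprocessed = isTRUE(meta$preprocessed))
}

#' Write the ground-truth sidecar
#'
#' Serializes the full parameter set of a synthetic system (per-channel
#' `a`, `b`, `c` blocks and the coupling array `d`), the gating mode, the
#' noise level and the seed as JSON next to the recording container.
#'
#' @param system a [sample_ground_truth_system] result.
#' @param path file path for the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(system, path) {
  obj <- list(family = system$family, gating = system$gating,
              L = system$L, M = system$M, P = system$P, C = system$C,
              noise_sd = system$noise_sd, margin = system$margin,
              seed = system$seed,
              # flat column-major vectors: shapes are reconstructed from
              # (L, M, P, C) so the round trip is representation-exact
              a = as.vector(system$a), b = as.vector(system$b),
              c = as.vector(system$c),
              d = as.vector(system$d), d_dim = dim(system$d))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ground-truth sidecar
#'
#' @param path JSON file written by [write_ground_truth].
#' @param geometry the [electrode_geometry] to attach.
#' @return A `ground_truth_system`.
#' @export
read_ground_truth <- function(path, geometry) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m, nr) {
    if (nr == 0L) matrix(0, 0, o$C)
    else matrix(as.numeric(unlist(m)), nrow = nr, ncol = o$C)
  }
  structure(
    list(a = as_mat(o$a, o$L), b = as_mat(o$b, o$M), c = as_mat(o$c, o$L),
         d = array(as.numeric(o$d), dim = o$d_dim),
         family = o$family, gating = o$gating,
         L = o$L, M = o$M, P = o$P, C = o$C,
         noise_sd = o$noise_sd, margin = o$margin,
         geometry = geometry, seed = o$seed),
    class = "ground_truth_system")
}
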