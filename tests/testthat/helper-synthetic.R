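# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

# A small synthetic world: geometry + system + schedule + recording +
# windows, all from one seed.
quick_world <- function(seed = 1L, C = 4L, L = 3L, M = 2L, P = 0L,
                        family = "SL_ARX", gating = NULL,
                        frequencies = c(10, 50, 200), reps = 3L,
                        noise_sd = 0.1, gap_ms = 1500,
                        coupling_band = NULL, extent_mm = 120,
                        n_off_windows = 0L, margin = 0.95) {
  geom <- make_electrode_geometry(C, extent_mm, seed = seed)
  spec <- model_spec(1L, L = L, M = M, P = P, family = family,
                     gating = gating)
  sys <- sample_ground_truth_system(spec, geom, noise_sd = noise_sd,
                                    coupling_band = coupling_band,
                                    margin = margin, seed = seed)
  sched <- make_schedule(frequencies = frequencies, reps = reps,
                         gap_ms = gap_ms, seed = seed)
  rec <- simulate_recording(sys, sched, seed = seed)
  ws <- extract_windows_and_folds(rec, seed = seed,
                                  n_off_windows = n_off_windows)
  list(geom = geom, spec = spec, sys = sys, sched = sched,
       rec = rec, ws = ws)
}

# True theta in feature layout for channel k of a world.
true_theta <- function(world, k = 1L, P = NULL) {
  sp <- world$spec
  sp$k <- as.integer(k)
  if (!is.null(P)) sp$P <- as.integer(P)
  sp$sources <- NULL
  sp <- modifyList(sp, list())
  class(sp) <- "model_spec"
  stimdyn:::theta_true(world$sys,
                       modifyList(sp, list(sources =
                         stimdyn:::spec_sources(sp, world$sys$C))))
}

# Power of a series at frequency f0 (Hz) via the DFT bin nearest f0.
power_at <- function(x, f0, fs = 1000) {
  n <- length(x)
  bin <- round(f0 / fs * n) + 1L
  Mod(stats::fft(x)[bin])^2 / n
}
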