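# Configuration, end-to-end pipeline, and the command-line entry point.

#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its default. Configs are plain lists
#' serialized as JSON; [run_pipeline] validates required keys.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    # synthetic world
    n_channels = 8L, extent_mm = 120, family = "SL_ARX",
    gating = "switched", L = 4L, M = 3L, P = 1L,
    noise_sd = 0.1, margin = 0.95, coupling_band = NULL,
    frequencies = c(10, 25, 50, 100, 200), A_safe = 2.0,
    amplitudes = NULL, reps = 3L, gap_ms = 1500,
    # preprocessing
    preprocess = FALSE, notch_freqs = c(60, 120, 180),
    onset_search_halfwidth_ms = 50, onset_threshold_mult = 5,
    # learning
    lambda = 0.1,
    L_grid = c(0L, 1L, 2L, 4L, 8L), M_grid = c(0L, 2L, 3L),
    P_grid = c(1L, 3L, 5L),
    tau_cap = 20L,
    # inference
    n_boot = 100L, alpha = 0.05,
    # network analysis
    ma_width_mm = 20, bin_width_mm = 20, elimination_threshold = 0.02,
    # stages
    stages = c("simulate", "select_order", "compare_families", "causal",
               "distance", "report"))
}

required_config_keys <- c("seed", "n_channels", "family", "L", "M",
                          "noise_sd", "lambda", "n_boot", "alpha",
                          "stages")

validate_config <- function(config) {
  miss <- setdiff(required_config_keys, names(config))
  if (length(miss) > 0L)
    stopf("config is missing required key(s): %s",
          paste(miss, collapse = ", "))
  config
}

#' Read a JSON pipeline configuration
#'
#' Missing keys fall back to [default_config] values; required keys are
#' checked after merging.
#' @param path JSON file.
#' @return validated config list.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(utils::modifyList(default_config(), user))
}

#' Run the full synthetic pipeline
#'
#' Executes the configured stages in order -- simulate, (preprocess),
#' select_order, compare_families, causal, distance, generalize, report --
#' writing tidy CSV result tables and a JSON run manifest to `out_dir`.
#' Reruns with the same config and seed reproduce all outputs bitwise.
#'
#' @param config a config list (see [default_config] / [read_config]).
#' @param out_dir output directory.
#' @return list of stage results, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- utils::modifyList(default_config(), validate_config(config))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  state <- new.env(parent = emptyenv())
  for (stage in config$stages) {
    fn <- pipeline_stages[[stage]]
    if (is.null(fn)) stopf("unknown pipeline stage '%s'", stage)
    res[[stage]] <- tryCatch(
      fn(config, state, out_dir),
      error = function(e) stopf("stage '%s' failed: %s",
                                stage, conditionMessage(e)))
  }
  manifest <- list(config = config, stages_run = config$stages,
                   package_version = as.character(
                     utils::packageVersion("stimdyn")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

stage_simulate <- function(config, state, out_dir) {
  geom <- make_electrode_geometry(config$n_channels, config$extent_mm,
                                  seed = config$seed)
  spec <- model_spec(k = 1L, L = config$L, M = config$M,
                     P = config$P %||% 0L,
                     family = config$family, gating = config$gating)
  sys <- sample_ground_truth_system(
    spec, geom, coupling_band = config$coupling_band,
    noise_sd = config$noise_sd, margin = config$margin,
    seed = config$seed)
  sched <- make_schedule(frequencies = config$frequencies,
                         amplitudes = config$amplitudes,
                         reps = config$reps, gap_ms = config$gap_ms,
                         A_safe = config$A_safe, seed = config$seed)
  rec <- simulate_recording(sys, sched, seed = config$seed)
  if (isTRUE(config$preprocess)) rec <- preprocess_signal(rec)
  ws <- extract_windows_and_folds(rec, seed = config$seed)
  state$rec <- rec; state$ws <- ws; state$system <- sys
  write_recording(rec, file.path(out_dir, "recording"))
  write_ground_truth(sys, file.path(out_dir, "ground_truth.json"))
  list(recording = rec, system = sys)
}

need_data <- function(config, state, out_dir) {
  if (is.null(state$rec)) {
    cdir <- config$input %||% file.path(out_dir, "recording")
    if (!dir.exists(cdir))
      stopf("no recording available; run the simulate stage or set $input")
    state$rec <- read_recording(cdir)
    state$ws <- extract_windows_and_folds(state$rec, seed = config$seed)
  }
  invisible(NULL)
}

stage_select_order <- function(config, state, out_dir) {
  need_data(config, state, out_dir)
  gs <- grid_search_orders(state$rec, state$ws, k = 1L,
                           L_grid = config$L_grid, M_grid = config$M_grid,
                           lambda = config$lambda, alpha = config$alpha)
  write_num_csv(gs$table, file.path(out_dir, "order_selection.csv"))
  state$LM <- gs$mean_best
  gs
}

stage_compare_families <- function(config, state, out_dir) {
  need_data(config, state, out_dir)
  L <- unname((state$LM %||% c(L = config$L))["L"])
  M <- unname((state$LM %||% c(L = 0, M = config$M))["M"])
  if (L == 0L) L <- max(1L, config$L)
  fams <- list(ARX = model_spec(1L, L = L, M = M, family = "ARX"),
               SL_ARX = model_spec(1L, L = L, M = M, family = "SL_ARX",
                                   gating = "switched"),
               AWSL_ARX = model_spec(1L, L = L, M = M, family = "SL_ARX",
                                     gating = "amplitude"),
               BL_ARX = model_spec(1L, L = L, M = M, family = "SL_ARX",
                                   gating = "bilinear"))
  rows <- list()
  for (k in seq_len(state$rec$C)) {
    for (nm in names(fams)) {
      sp <- utils::modifyList(fams[[nm]], list(k = k))
      class(sp) <- "model_spec"
      ds <- build_features(state$rec, state$ws, sp)
      ev <- evaluate_model(fit_ridge(ds, config$lambda), ds)
      rows[[length(rows) + 1L]] <- data.frame(
        channel = k, model = nm, mse = ev$mse, nmse = ev$nmse, n = ev$n)
    }
  }
  tab <- do.call(rbind, rows)
  mse_tab <- stats::reshape(tab[, c("channel", "model", "mse")],
                            idvar = "channel", timevar = "model",
                            direction = "wide")
  wr <- win_rate(as.matrix(mse_tab[, -1L]),
                 n_params = vapply(fams, function(s)
                   spec_n_params(s, 0L), numeric(1)))
  names(wr) <- names(fams)
  write_num_csv(tab, file.path(out_dir, "family_comparison.csv"))
  list(table = tab, win_rate = wr)
}

stage_causal <- function(config, state, out_dir) {
  need_data(config, state, out_dir)
  sp <- model_spec(1L, L = config$L, M = config$M, family = "SL_ARX",
                   gating = "switched")
  rows <- list()
  for (k in seq_len(state$rec$C)) {
    spk <- utils::modifyList(sp, list(k = k)); class(spk) <- "model_spec"
    bt <- bootstrap_input_test(state$rec, state$ws, spk,
                               n_boot = config$n_boot,
                               alpha = config$alpha,
                               lambda = config$lambda,
                               seed = child_seed(config$seed, paste0("c", k)))
    rows[[length(rows) + 1L]] <- data.frame(
      channel = k, test = "input", observed_mse = bt$observed_mse,
      p = bt$p, reject = bt$reject)
  }
  tab <- do.call(rbind, rows)
  write_num_csv(tab, file.path(out_dir, "causal_tests.csv"))
  tab
}

stage_distance <- function(config, state, out_dir) {
  need_data(config, state, out_dir)
  base <- model_spec(1L, L = config$L, M = config$M, family = "SL_ARX",
                     gating = "switched")
  prof <- mse_advantage_profile(state$rec, state$ws, base,
                                P = max(1L, config$P %||% 1L),
                                lambda = config$lambda,
                                ma_width = config$ma_width_mm)
  write_num_csv(prof$profile, file.path(out_dir, "distance_profile.csv"))
  prof
}

stage_generalize <- function(config, state, out_dir) {
  need_data(config, state, out_dir)
  ws <- extract_windows_and_folds(state$rec, seed = config$seed,
                                  n_off_windows = 6L)
  sp <- model_spec(1L, L = config$L, M = config$M, family = "SL_ARX",
                   gating = "switched")
  fs <- frequency_subset_experiment(state$rec, ws, sp,
                                    conditions = c(0, config$frequencies),
                                    lambda = config$lambda)
  write_num_csv(fs$table, file.path(out_dir, "frequency_subsets.csv"))
  fs
}

stage_report <- function(config, state, out_dir) {
  files <- list.files(out_dir, pattern = "\\.csv$")
  writeLines(c("stimdyn pipeline results", files),
             file.path(out_dir, "REPORT.txt"))
  files
}

pipeline_stages <- list(
  simulate = stage_simulate,
  preprocess = function(config, state, out_dir) {
    need_data(config, state, out_dir)
    state$rec <- preprocess_signal(state$rec)
    write_recording(state$rec, file.path(out_dir, "recording"))
    invisible(TRUE)
  },
  select_order = stage_select_order,
  compare_families = stage_compare_families,
  causal = stage_causal,
  distance = stage_distance,
  generalize = stage_generalize,
  report = stage_report)

#' Command-line entry point
#'
#' Subcommands: `simulate`, `preprocess`, `fit`, `select-order`,
#' `compare-families`, `causal`, `distance`, `eliminate`, `generalize`,
#' `report`, `pipeline`. Global flags: `--config <json>`, `--seed <int>`,
#' `--out <dir>`, `--log-level <level>`. Returns 0 on success, nonzero
#' with a one-line diagnostic on error. Install target:
#' `Rscript -e 'stimdyn::cli_main()' <subcommand> [flags]` or the script
#' in `inst/cli/stimdyn`.
#'
#' @param args character vector (defaults to [commandArgs]).
#' @return integer exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L)
      stopf("usage: stimdyn <subcommand> [--config f] [--seed n] [--out d]")
    cmd <- args[[1L]]
    opts <- parse_cli_flags(args[-1L])
    config <- if (!is.null(opts$config)) read_config(opts$config)
              else default_config()
    if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
    out_dir <- opts$out %||% "stimdyn_results"
    stage_map <- c("simulate" = "simulate", "preprocess" = "preprocess",
                   "fit" = "compare_families",
                   "select-order" = "select_order",
                   "compare-families" = "compare_families",
                   "causal" = "causal", "distance" = "distance",
                   "eliminate" = "distance", "generalize" = "generalize",
                   "report" = "report")
    if (cmd == "pipeline") {
      run_pipeline(config, out_dir)
    } else if (cmd %in% names(stage_map)) {
      stages <- unique(c(if (stage_map[[cmd]] != "simulate") "simulate",
                         stage_map[[cmd]]))
      config$stages <- stages
      run_pipeline(config, out_dir)
    } else {
      stopf("unknown subcommand '%s'", cmd)
    }
    0L
  }, error = function(e) {
    message("stimdyn: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stopf("unexpected argument '%s'", a)
    key <- sub("^--", "", a)
    if (i == length(args)) stopf("flag %s needs a value", a)
    opts[[sub("-", "_", key)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  opts
}
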