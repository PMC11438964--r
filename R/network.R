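# Distance-resolved network-interaction analyses: scalar-vs-vector MSE
# advantage profiles, backward elimination of source-electrode groups, and
# the sigmoid summary of the elimination curve.

vector_family <- function(family) {
  switch(family,
         AR = "VAR", ARX = "VARX", SL_AR = "SL_VAR", SL_ARX = "SL_VARX",
         family)
}

scalar_family <- function(family) {
  switch(family,
         VAR = "AR", VARX = "ARX", SL_VAR = "SL_AR", SL_VARX = "SL_ARX",
         family)
}

#' Distance profile of the network-modeling advantage
#'
#' For every non-stimulation channel, fits a scalar model (no network
#' block) and a vector model (lagged history of all other channels) on
#' identical folds and computes the advantage
#' `MSE_scalar - MSE_vector`. The per-channel advantages are plotted
#' against channel-to-anode distance and summarized by a moving average on
#' a millimetre grid; the peak of the smoothed curve localizes the distance
#' range where network interactions carry predictive information.
#'
#' @param rec a [recording].
#' @param ws a [extract_windows_and_folds] result.
#' @param base_spec a scalar-family [model_spec] template (its `k` is
#'   overridden per channel; `P` is used for the vector variant).
#' @param P network lags for the vector model.
#' @param lambda ridge penalty.
#' @param ma_width moving-average window width (mm).
#' @param grid_step moving-average grid step (mm).
#' @param min_channels smallest number of channels per moving-average
#'   window; windows with fewer are masked.
#' @param events optional corrected event table.
#' @return An object of class `distance_profile`: `profile` (per-channel
#'   data.frame), `curve` (grid, smoothed advantage), `peak_mm`.
#' @export
mse_advantage_profile <- function(rec, ws, base_spec, P = 1L,
                                  lambda = 0.1, ma_width = 20,
                                  grid_step = 1, min_channels = 3L,
                                  events = NULL) {
  anode <- rec$geometry$anode_index
  chans <- setdiff(seq_len(rec$C), anode)
  if (length(chans) < 2L) stopf("need at least 2 non-stimulation channels")
  rows <- lapply(chans, function(k) {
    sc <- modifyList(base_spec, list(k = as.integer(k), P = 0L,
                                     family = scalar_family(base_spec$family),
                                     sources = NULL))
    class(sc) <- "model_spec"
    vc <- modifyList(base_spec, list(k = as.integer(k), P = as.integer(P),
                                     family = vector_family(base_spec$family),
                                     sources = NULL))
    class(vc) <- "model_spec"
    ds_s <- build_features(rec, ws, sc, events = events)
    ds_v <- build_features(rec, ws, vc, events = events)
    ms <- evaluate_model(fit_ridge(ds_s, lambda), ds_s)$mse
    mv <- evaluate_model(fit_ridge(ds_v, lambda), ds_v)$mse
    data.frame(channel = k,
               dist_mm = rec$geometry$pairwise_dist[k, anode],
               mse_scalar = ms, mse_vector = mv, advantage = ms - mv)
  })
  prof <- do.call(rbind, rows)
  grid <- seq(0, max(prof$dist_mm), by = grid_step)
  val <- vapply(grid, function(g) {
    sel <- abs(prof$dist_mm - g) <= ma_width / 2
    if (sum(sel) >= min_channels) mean(prof$advantage[sel]) else NA_real_
  }, numeric(1))
  if (all(is.na(val))) {           # too few channels anywhere: no smoothing
    peak <- prof$dist_mm[which.max(prof$advantage)]
  } else {
    peak <- grid[which.max(val)]
  }
  structure(list(profile = prof,
                 curve = data.frame(dist_mm = grid, advantage = val),
                 peak_mm = peak, ma_width = ma_width),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("<distance_profile> %d channels, advantage peak at %.0f mm\n",
              nrow(x$profile), x$peak_mm))
  invisible(x)
}

#' Backward elimination of source electrodes by distance bin
#'
#' Groups the network source electrodes of a channel by their distance to
#' that channel, then refits the model with each group's terms removed.
#' The channel is "unimpacted" by a group when the relative increase in
#' held-out NMSE stays below `threshold` (2% by default). Removing every
#' group reproduces the scalar model exactly.
#'
#' @param rec,ws,events as in [mse_advantage_profile].
#' @param k the modeled channel.
#' @param full_spec a vector-family [model_spec] for channel `k`.
#' @param breaks distance bin edges (mm); default 20 mm bins spanning the
#'   observed source distances.
#' @param lambda ridge penalty.
#' @param threshold relative NMSE-increase threshold.
#' @return list with `bins` (data.frame: bin edges, source count,
#'   `nmse_reduced`, `rel_increase`, `unimpacted`), `nmse_full`, `skipped`
#'   (empty bins).
#' @export
backward_elimination <- function(rec, ws, k, full_spec, breaks = NULL,
                                 lambda = 0.1, threshold = 0.02,
                                 events = NULL) {
  full_spec <- modifyList(full_spec, list(k = as.integer(k)))
  class(full_spec) <- "model_spec"
  src_all <- spec_sources(full_spec, rec$C)
  if (length(src_all) == 0L) stopf("spec has no network sources")
  dist_k <- rec$geometry$pairwise_dist[k, src_all]
  if (is.null(breaks))
    breaks <- seq(0, max(dist_k) + 20, by = 20)
  ds_full <- build_features(rec, ws, full_spec, events = events)
  nmse_full <- evaluate_model(fit_ridge(ds_full, lambda), ds_full)$nmse
  out <- list(); skipped <- list()
  for (bi in seq_len(length(breaks) - 1L)) {
    lo <- breaks[bi]; hi <- breaks[bi + 1L]
    inbin <- src_all[dist_k >= lo & dist_k < hi]
    if (length(inbin) == 0L) {
      skipped[[length(skipped) + 1L]] <- c(lo, hi)
      next
    }
    keep <- setdiff(src_all, inbin)
    red <- modifyList(full_spec, list(sources = keep))
    if (length(keep) == 0L)
      red <- modifyList(red, list(family = scalar_family(full_spec$family),
                                  P = 0L, sources = NULL))
    class(red) <- "model_spec"
    ds_r <- build_features(rec, ws, red, events = events)
    nm <- evaluate_model(fit_ridge(ds_r, lambda), ds_r)$nmse
    rel <- (nm - nmse_full) / nmse_full
    out[[length(out) + 1L]] <- data.frame(
      bin_lo = lo, bin_hi = hi, n_sources = length(inbin),
      nmse_reduced = nm, rel_increase = rel,
      unimpacted = rel < threshold)
  }
  list(bins = do.call(rbind, out), nmse_full = nmse_full,
       skipped = skipped, threshold = threshold)
}

#' Fit a four-parameter sigmoid to an elimination curve
#'
#' Least-squares fit of `y = B + A / (1 + exp(-(x - x0) / s))` with an
#' F-test against the constant model as the trend diagnostic.
#'
#' @param x distance bin centres (mm); at least 4.
#' @param y response (e.g. % of channels unimpacted).
#' @return list with `pars` (`A`, `x0`, `s`, `B`), `rss`, `f_stat`,
#'   `p_value` (F-test vs constant), `converged`.
#' @export
fit_sigmoid <- function(x, y) {
  if (length(x) < 4L) stopf("need at least 4 points")
  sig <- function(p) p[4] + p[1] / (1 + exp(-(x - p[2]) / p[3]))
  rss_of <- function(p) sum((y - sig(p))^2)
  start <- c(A = max(y) - min(y), x0 = stats::median(x),
             s = diff(range(x)) / 5, B = min(y))
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(y ~ B + A / (1 + exp(-(x - x0) / s)),
               data = data.frame(x = x, y = y),
               start = as.list(start),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = TRUE))),
    error = function(e) NULL)
  pars <- NULL; converged <- FALSE
  if (!is.null(fit) && isTRUE(fit$convInfo$isConv)) {
    pars <- stats::coef(fit)[c("A", "x0", "s", "B")]
    converged <- TRUE
  } else {
    st <- if (!is.null(fit)) stats::coef(fit) else start
    opt <- stats::optim(st, rss_of, method = "Nelder-Mead",
                        control = list(maxit = 5000))
    pars <- opt$par[c("A", "x0", "s", "B")]
    converged <- opt$convergence == 0
  }
  rss1 <- rss_of(pars)
  rss0 <- sum((y - mean(y))^2)
  dof <- length(x) - 4L
  f_stat <- if (dof > 0L) ((rss0 - rss1) / 3) / (rss1 / dof) else NA_real_
  p_value <- if (is.finite(f_stat))
    stats::pf(f_stat, 3, dof, lower.tail = FALSE) else NA_real_
  if (!converged) {
    warnf("sigmoid fit did not converge; parameters omitted")
    pars <- NULL
  }
  list(pars = pars, rss = rss1, f_stat = f_stat, p_value = p_value,
       converged = converged)
}

#' Scalar vs vector modeling of the stimulation channel
#'
#' Fits a switched ARX and a switched VARX model for the anode channel on
#' identical folds and reports the relative MSE improvement of including
#' network terms.
#'
#' @param rec,ws,events as in [mse_advantage_profile].
#' @param L,M,P lag orders.
#' @param lambda ridge penalty.
#' @return list with `mse_arx`, `mse_varx`, `rel_improvement`
#'   (`(mse_arx - mse_varx) / mse_arx`), `winner`.
#' @export
stim_site_comparison <- function(rec, ws, L = 10L, M = 5L, P = 1L,
                                 lambda = 0.1, events = NULL) {
  anode <- rec$geometry$anode_index
  if (is.null(anode)) stopf("no anode channel")
  if (rec$C < 2L) stopf("vector model undefined with a single channel")
  sp_a <- model_spec(k = anode, L = L, M = M, family = "SL_ARX",
                     gating = "switched")
  sp_v <- model_spec(k = anode, L = L, M = M, P = P, family = "SL_VARX",
                     gating = "switched")
  ds_a <- build_features(rec, ws, sp_a, events = events)
  ds_v <- build_features(rec, ws, sp_v, events = events)
  ma <- evaluate_model(fit_ridge(ds_a, lambda), ds_a)$mse
  mv <- evaluate_model(fit_ridge(ds_v, lambda), ds_v)$mse
  list(mse_arx = ma, mse_varx = mv,
       rel_improvement = (ma - mv) / ma,
       winner = if (mv < ma) "SL_VARX" else "SL_ARX")
}
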