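#' Build the regression dataset for one channel model
#'
#' Assembles the feature matrix `X` and increment targets
#' `dy_k(t) = y_k(t+1) - y_k(t)` over all extracted windows. Row layout per
#' sample `t` (0-based): autoregressive block `y_k(t-1..t-L)` (or the
#' delay-embedded lags `t - tau ... t - L tau` for sparse specs), then the
#' gated interaction block `U(t) * y_k^L(t)`, then input lags
#' `u(t-1..t-M)`, then one `P`-lag block per network source channel.
#' Lag history never crosses a window boundary; rows whose full history or
#' target fall outside their window are excluded. Fold membership of a row
#' is the fold of its target sample.
#'
#' @param rec a [recording].
#' @param ws a [extract_windows_and_folds] result.
#' @param spec a [model_spec].
#' @param events event table used for input encoding; defaults to the
#'   recording's schedule (pass corrected events if onsets were adjusted).
#' @return An object of class `regression_dataset` with fields `X`, `dy`,
#'   `window`, `fold`, `is_test`, `t`, `y_t`, `spec`, `blocks` (column index
#'   list) and `n`.
#' @export
build_features <- function(rec, ws, spec, events = NULL) {
  blocks <- family_blocks(spec$family)
  ev <- events %||% rec$schedule$events
  C <- rec$C
  src <- spec_sources(spec, C)
  L <- spec$L; M <- spec$M; P <- spec$P
  p <- spec_n_params(spec, length(src))
  if (p == 0L) stopf("empty feature space: no free lag blocks")
  a_lags <- if (spec$sparse) spec$tau * seq_len(L) else seq_len(L)
  maxlag <- max(a_lags, if (blocks$has_b) M else 0L,
                if (length(src)) P else 0L, 1L)

  u <- encode_input(ev, rec$T)
  U <- gating_signal(u, ev, spec$gating)
  y <- rec$signal[spec$k, ]

  cols <- list(a = seq_len(L))
  nxt <- L
  if (blocks$has_c) { cols$c <- nxt + seq_len(L); nxt <- nxt + L }
  if (blocks$has_b) { cols$b <- nxt + seq_len(M); nxt <- nxt + M }
  if (length(src)) {
    cols$d <- stats::setNames(
      lapply(seq_along(src), function(j) nxt + (j - 1L) * P + seq_len(P)),
      as.character(src))
    nxt <- nxt + length(src) * P
  }

  Xs <- list(); dys <- list(); wins <- list(); folds <- list()
  ts <- list(); yts <- list()
  W <- ws$windows
  for (w in seq_len(nrow(W))) {
    t_lo <- W$start[w] + maxlag
    t_hi <- W$end[w] - 2L
    if (t_hi < t_lo) next
    s <- (t_lo:t_hi) + 1L                       # R index of current sample
    n <- length(s)
    Xw <- matrix(0, nrow = n, ncol = nxt)
    for (j in seq_len(L)) Xw[, cols$a[j]] <- y[s - a_lags[j]]
    if (blocks$has_c)
      for (j in seq_len(L)) Xw[, cols$c[j]] <- U[s] * y[s - a_lags[j]]
    if (blocks$has_b)
      for (j in seq_len(M)) Xw[, cols$b[j]] <- u[s - j]
    if (length(src))
      for (jj in seq_along(src)) {
        yi <- rec$signal[src[jj], ]
        for (j in seq_len(P)) Xw[, cols$d[[jj]][j]] <- yi[s - j]
      }
    Xs[[length(Xs) + 1L]] <- Xw
    dys[[length(dys) + 1L]] <- y[s + 1L] - y[s]
    wins[[length(wins) + 1L]] <- rep(w, n)
    folds[[length(folds) + 1L]] <- fold_of_sample(ws, w, s)  # target t+1
    ts[[length(ts) + 1L]] <- s - 1L
    yts[[length(yts) + 1L]] <- y[s]
  }
  if (length(Xs) == 0L) stopf("no rows: windows shorter than the lag span")
  win_id <- unlist(wins)
  fold <- unlist(folds)
  structure(
    list(X = do.call(rbind, Xs), dy = unlist(dys),
         window = win_id, fold = fold,
         is_test = fold == W$test_fold[win_id],
         t = unlist(ts), y_t = unlist(yts),
         spec = spec, sources = src, blocks = cols,
         n = length(win_id)),
    class = "regression_dataset")
}

#' @export
print.regression_dataset <- function(x, ...) {
  cat(sprintf("<regression_dataset> %d rows x %d features (%s, channel %d)\n",
              x$n, ncol(x$X), x$spec$family, x$spec$k))
  invisible(x)
}

#' One-step prediction
#'
#' @param model a [fit_ridge] result.
#' @param X feature row (vector) or matrix built under the model's spec.
#' @param y_t current sample value(s); when supplied the predicted next
#'   sample `y(t) + dy` is returned alongside the increment.
#' @return list with `dy` and (when `y_t` given) `y_next`.
#' @export
predict_one_step <- function(model, X, y_t = NULL) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(model$theta))
    stopf("feature dimension %d does not match theta length %d",
          ncol(X), length(model$theta))
  dy <- drop(X %*% model$theta)
  out <- list(dy = dy)
  if (!is.null(y_t)) out$y_next <- y_t + dy
  out
}

#' Iterated k-step-ahead rollout
#'
#' Feeds one-step predictions back as autoregressive history to forecast
#' `n_steps` samples beyond the supplied history. Input and gating series
#' must cover the forecast horizon; network source channels, if any, are
#' treated as known exogenous series.
#'
#' @param model a [fit_ridge] result whose spec has `L >= 1`.
#' @param y_hist numeric vector of past samples of the target channel, the
#'   last element being the current sample; must cover the spec's lag span.
#' @param u,U input and gating series aligned with `y_hist` and extending at
#'   least `n_steps` beyond it.
#' @param n_steps forecast horizon (k = 1 reproduces [predict_one_step]).
#' @param sources optional matrix (one row per network source, in the order
#'   of the spec's source set) aligned like `u`.
#' @return numeric vector of the `n_steps` predicted samples.
#' @export
rollout <- function(model, y_hist, u, U, n_steps, sources = NULL) {
  spec <- model$spec
  blocks <- family_blocks(spec$family)
  L <- spec$L; M <- spec$M; P <- spec$P
  a_lags <- if (spec$sparse) spec$tau * seq_len(L) else seq_len(L)
  maxlag <- max(a_lags, if (blocks$has_b) M else 0L, 1L)
  H <- length(y_hist)
  if (H < maxlag) stopf("history of length %d is shorter than lag span %d",
                        H, maxlag)
  need <- H + n_steps
  if (length(u) < need - 1L || length(U) < need - 1L)
    stopf("input series must cover the forecast horizon")
  nsrc <- length(model$sources %||% integer(0))
  if (nsrc > 0L && (is.null(sources) || nrow(sources) != nsrc))
    stopf("network model needs a `sources` matrix with %d rows", nsrc)
  y <- c(y_hist, numeric(n_steps))
  th <- model$theta; cols <- model$blocks
  for (s in H + seq_len(n_steps) - 1L) {
    x <- numeric(length(th))
    x[cols$a] <- y[s - a_lags]
    if (!is.null(cols$c)) x[cols$c] <- U[s] * y[s - a_lags]
    if (!is.null(cols$b)) x[cols$b] <- u[s - seq_len(M)]
    if (nsrc > 0L)
      for (jj in seq_len(nsrc)) x[cols$d[[jj]]] <- sources[jj, s - seq_len(P)]
    y[s + 1L] <- y[s] + sum(th * x)
  }
  y[H + seq_len(n_steps)]
}

#' Select the delay-embedding time by auto mutual information
#'
#' Estimates the mutual information between `x(t)` and `x(t - l)` with an
#' equal-width 2-D histogram and returns the first local minimum of the
#' resulting lag profile, clipped to `[1, cap]`. A monotonically decreasing
#' profile (slow drift) returns `cap`; a profile that rises immediately
#' (white noise) returns 1.
#'
#' @param x numeric series.
#' @param cap largest admissible delay (samples).
#' @param bins histogram bins per axis.
#' @return integer delay time `tau`.
#' @export
select_tau <- function(x, cap = 20L, bins = 16L) {
  if (stats::sd(x) < 1e-12) stopf("constant series: tau undefined")
  if (length(x) < 4L * cap) stopf("series too short relative to cap")
  ami <- vapply(seq_len(cap + 1L), function(l) {
    n <- length(x) - l
    hist_mi(x[seq_len(n)], x[seq_len(n) + l], bins)
  }, numeric(1))
  for (l in seq_len(cap - 1L)) {
    if (ami[l + 1L] > ami[l]) return(l)     # ami rises after lag l
  }
  as.integer(cap)
}

hist_mi <- function(x, y, bins) {
  bx <- cut(x, breaks = bins, labels = FALSE)
  by <- cut(y, breaks = bins, labels = FALSE)
  pj <- table(bx, by) / length(x)
  px <- rowSums(pj); py <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(px, py)[nz]))
}
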