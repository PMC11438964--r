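#' Ridge estimation of the model parameters
#'
#' Minimizes `(1/N) sum_t (dy(t) - theta' x(t))^2 + lambda ||theta||^2`,
#' i.e. solves the normal equations `(X'X + N lambda I) theta = X' dy`
#' (note the `N` factor induced by the `1/N` in the MSE term). No intercept
#' is fitted: signals are z-scored upstream. With `lambda = 0` and a
#' singular Gram matrix the minimum-norm least-squares solution is returned
#' with a warning.
#'
#' @param dataset a [build_features] result.
#' @param lambda ridge penalty (default 0.1, the pipeline-wide setting).
#' @param rows `"train"` (default; rows outside each window's held-out
#'   fold), `"all"`, or a logical/integer row selector.
#' @return An object of class `fitted_model`: `theta`, `lambda`, `spec`,
#'   `blocks`, `sources`, `n_train`.
#' @export
fit_ridge <- function(dataset, lambda = 0.1, rows = "train") {
  sel <- resolve_rows(dataset, rows)
  X <- dataset$X[sel, , drop = FALSE]
  dy <- dataset$dy[sel]
  N <- nrow(X)
  if (N == 0L) stopf("no rows selected for fitting")
  if (lambda < 0) stopf("lambda must be >= 0")
  theta <- ridge_solve(crossprod(X), crossprod(X, dy), N * lambda)
  structure(
    list(theta = drop(theta), lambda = lambda, spec = dataset$spec,
         blocks = dataset$blocks, sources = dataset$sources,
         n_train = N),
    class = "fitted_model")
}

resolve_rows <- function(dataset, rows) {
  if (is.character(rows)) {
    switch(match.arg(rows, c("train", "test", "all")),
           train = !dataset$is_test,
           test = dataset$is_test,
           all = rep(TRUE, dataset$n))
  } else rows
}

# Solve (G + ridge I) theta = g; SPD factorization with min-norm fallback.
ridge_solve <- function(G, g, ridge) {
  p <- nrow(G)
  A <- G + diag(ridge, p)
  th <- tryCatch(
    backsolve(chol(A), forwardsolve(t(chol(A)), g)),
    error = function(e) NULL)
  if (is.null(th)) {
    if (ridge == 0) warnf("singular system with lambda = 0; %s",
                          "returning the minimum-norm solution")
    sv <- svd(A)
    tol <- max(dim(A)) * .Machine$double.eps * max(sv$d)
    dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
    th <- sv$v %*% (dinv * crossprod(sv$u, g))
  }
  th
}

#' Evaluate a fitted model on a dataset
#'
#' @param model a [fit_ridge] result.
#' @param dataset a [build_features] result with matching feature layout.
#' @param rows `"test"` (default), `"train"`, `"all"`, or a row selector.
#' @return list with `mse`, `nmse`, `n`, and `window_mse` (named per-window
#'   mean squared error over the selected rows).
#' @export
evaluate_model <- function(model, dataset, rows = "test") {
  sel <- resolve_rows(dataset, rows)
  X <- dataset$X[sel, , drop = FALSE]
  dy <- dataset$dy[sel]
  e2 <- (dy - drop(X %*% model$theta))^2
  wm <- tapply(e2, dataset$window[sel], mean)
  list(mse = mean(e2), nmse = nmse_from_errors(e2, dy), n = length(dy),
       window_mse = wm)
}

#' Hierarchical order selection: grid search over (L, M) for an ARX model
#'
#' Fits ARX models on every pair of the autoregressive and input lag grids
#' (default grids `L in {0, 1, 50, 100, ..., 500}`,
#' `M in {0, 100, 200, 300}`) and reports the pair minimizing the mean
#' held-out MSE as well as the winner of the Wilcoxon-based median
#' criterion ([median_best]). All cells share one feature matrix restricted
#' to rows with full history at the largest lags, so every cell is scored
#' on identical samples. Ties go to the smallest `L`, then smallest `M`.
#'
#' @param rec a [recording].
#' @param ws a [extract_windows_and_folds] result.
#' @param k target channel.
#' @param L_grid,M_grid lag grids.
#' @param lambda ridge penalty.
#' @param alpha level for the median (signed-rank) criterion.
#' @param events optional corrected event table.
#' @return list with `mean_best`, `median_best` (each `c(L, M)`), `table`
#'   (per-cell mean/SEM of window MSE), and `window_mse` (cells x windows).
#' @export
grid_search_orders <- function(rec, ws, k = 1L,
                               L_grid = c(0L, 1L, seq(50L, 500L, 50L)),
                               M_grid = c(0L, 100L, 200L, 300L),
                               lambda = 0.1, alpha = 0.05, events = NULL) {
  if (length(L_grid) == 0L || length(M_grid) == 0L) stopf("empty grid")
  Lmax <- max(L_grid); Mmax <- max(M_grid)
  spec <- model_spec(k = k, L = Lmax, M = Mmax, family = "ARX")
  ds <- build_features(rec, ws, spec, events = events)
  tr <- !ds$is_test
  Xtr <- ds$X[tr, , drop = FALSE]; dytr <- ds$dy[tr]
  Xte <- ds$X[!tr, , drop = FALSE]; dyte <- ds$dy[!tr]
  wte <- ds$window[!tr]
  G <- crossprod(Xtr); g <- drop(crossprod(Xtr, dytr))
  N <- nrow(Xtr)
  wins <- sort(unique(ds$window))
  cells <- expand.grid(L = L_grid, M = M_grid, KEEP.OUT.ATTRS = FALSE)
  # tie-break order: smallest L, then smallest M
  cells <- cells[order(cells$L, cells$M), , drop = FALSE]
  rownames(cells) <- NULL
  nmcell <- nrow(cells)
  window_mse <- matrix(NA_real_, nmcell, length(wins),
                       dimnames = list(NULL, wins))
  mse_mean <- numeric(nmcell)
  for (ci in seq_len(nmcell)) {
    L <- cells$L[ci]; M <- cells$M[ci]
    idx <- c(ds$blocks$a[seq_len(L)], ds$blocks$b[seq_len(M)])
    pred <- if (length(idx) == 0L) {
      rep(0, length(dyte))
    } else {
      th <- ridge_solve(G[idx, idx, drop = FALSE], g[idx], N * lambda)
      drop(Xte[, idx, drop = FALSE] %*% th)
    }
    e2 <- (dyte - pred)^2
    wm <- tapply(e2, wte, mean)
    window_mse[ci, names(wm)] <- wm
    mse_mean[ci] <- mean(e2)
  }
  n_params <- cells$L + cells$M
  mean_best <- unlist(cells[which.min(mse_mean), ])
  med <- median_best(t(window_mse), n_params = n_params, alpha = alpha)
  cells$mse_mean <- mse_mean
  cells$mse_sem <- apply(window_mse, 1L, function(v)
    stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  list(mean_best = mean_best,
       median_best = unlist(cells[med$winner, c("L", "M")]),
       table = cells, window_mse = window_mse)
}

#' Refine the network lag order P
#'
#' With the family and `(L, M)` fixed, fits the model at each `P` of the
#' grid (default: 1 to 100 in steps of 10, plus 100) and returns the value
#' minimizing held-out MSE; ties go to the smallest `P`.
#'
#' @param rec,ws,events as in [grid_search_orders].
#' @param spec a [model_spec] of a network family; its `P` is overridden.
#' @param P_grid candidate network lags.
#' @param lambda ridge penalty.
#' @return list with `best_P`, `table`; when the spec has no network
#'   sources, `best_P = 0` with a note.
#' @export
select_network_lags <- function(rec, ws, spec,
                                P_grid = c(seq(1L, 91L, 10L), 100L),
                                lambda = 0.1, events = NULL) {
  if (length(P_grid) == 0L) stopf("empty grid")
  src <- spec_sources(modifyList(spec, list(P = 1L)), rec$C)
  if (length(src) == 0L)
    return(list(best_P = 0L, table = NULL,
                note = "no network sources; P = 0"))
  # one dataset at the largest P so every candidate is scored on
  # identical samples; smaller P uses a column subset
  Pmax <- max(P_grid)
  sp <- modifyList(spec, list(P = as.integer(Pmax)))
  class(sp) <- "model_spec"
  ds <- build_features(rec, ws, sp, events = events)
  tr <- !ds$is_test
  G <- crossprod(ds$X[tr, , drop = FALSE])
  g <- drop(crossprod(ds$X[tr, , drop = FALSE], ds$dy[tr]))
  N <- sum(tr)
  base_cols <- setdiff(seq_len(ncol(ds$X)), unlist(ds$blocks$d))
  mse <- vapply(sort(P_grid), function(P) {
    idx <- c(base_cols,
             unlist(lapply(ds$blocks$d, function(cc) cc[seq_len(P)])))
    th <- ridge_solve(G[idx, idx, drop = FALSE], g[idx], N * lambda)
    mean((ds$dy[!tr] -
            drop(ds$X[!tr, idx, drop = FALSE] %*% th))^2)
  }, numeric(1))
  best <- sort(P_grid)[which.min(mse)]
  list(best_P = as.integer(best),
       table = data.frame(P = sort(P_grid), mse = mse))
}

#' Ridge fit with a frozen autoregressive block
#'
#' Re-estimates only the non-autoregressive blocks of a dataset's spec
#' while pinning the `a` block to supplied values: the target becomes the
#' residual `dy - a_fixed' y^L` and the remaining columns are fit by ridge.
#' Used by the indirect linearity test, where `a` learned on STIM OFF data
#' is combined with an input block learned on STIM ON data.
#'
#' @param dataset a [build_features] result.
#' @param a_fixed numeric vector of length `L`.
#' @param lambda ridge penalty.
#' @param rows row selector as in [fit_ridge].
#' @return A `fitted_model` whose `a` block equals `a_fixed`.
#' @export
fit_constrained_stim <- function(dataset, a_fixed, lambda = 0.1,
                                 rows = "train") {
  acols <- dataset$blocks$a
  if (length(a_fixed) != length(acols))
    stopf("a_fixed has length %d but the spec has L = %d",
          length(a_fixed), length(acols))
  free <- setdiff(seq_len(ncol(dataset$X)), acols)
  theta <- numeric(ncol(dataset$X))
  theta[acols] <- a_fixed
  sel <- resolve_rows(dataset, rows)
  if (length(free) > 0L) {
    X <- dataset$X[sel, , drop = FALSE]
    resid <- dataset$dy[sel] - drop(X[, acols, drop = FALSE] %*% a_fixed)
    Xf <- X[, free, drop = FALSE]
    theta[free] <- drop(ridge_solve(crossprod(Xf), crossprod(Xf, resid),
                                    nrow(Xf) * lambda))
  }
  structure(
    list(theta = theta, lambda = lambda, spec = dataset$spec,
         blocks = dataset$blocks, sources = dataset$sources,
         n_train = sum(sel), constrained = "a"),
    class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model> %s channel %d, %d parameters, lambda=%.3g\n",
              x$spec$family, x$spec$k, length(x$theta), x$lambda))
  invisible(x)
}
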