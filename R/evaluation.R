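#' Normalized mean squared error
#'
#' Test MSE divided by the (population) variance of the targets over the
#' same samples, so that 0 is a perfect predictor and 1 is the
#' predict-no-change baseline on zero-mean targets. Comparable across
#' channels regardless of their residual scale.
#'
#' @param predictions,targets equal-length numeric vectors (`n >= 2`).
#' @return scalar NMSE.
#' @export
nmse <- function(predictions, targets) {
  if (length(predictions) != length(targets)) stopf("length mismatch")
  if (length(targets) < 2L) stopf("need at least 2 samples")
  nmse_from_errors((targets - predictions)^2, targets)
}

nmse_from_errors <- function(e2, targets) {
  v <- mean((targets - mean(targets))^2)
  if (v < 1e-300) stopf("zero target variance: NMSE undefined")
  mean(e2) / v
}

#' Win rate across channels
#'
#' Fraction of channels on which each model achieves the strictly smallest
#' error; exact ties are credited to the model with the fewest parameters.
#' Fractions sum to 1.
#'
#' @param mse_table channels x models numeric matrix.
#' @param n_params parameter count per model (tie-breaking).
#' @return named numeric vector of per-model win fractions.
#' @export
win_rate <- function(mse_table, n_params = NULL) {
  mse_table <- as.matrix(mse_table)
  if (nrow(mse_table) < 1L || ncol(mse_table) < 2L)
    stopf("need >= 1 channel and >= 2 models")
  m <- ncol(mse_table)
  n_params <- n_params %||% rep(0, m)
  wins <- numeric(m)
  for (ch in seq_len(nrow(mse_table))) {
    v <- mse_table[ch, ]
    best <- which(v == min(v))
    if (length(best) > 1L) best <- best[which.min(n_params[best])]
    wins[best] <- wins[best] + 1
  }
  out <- wins / nrow(mse_table)
  names(out) <- colnames(mse_table)
  out
}

#' Median-criterion model comparison (Wilcoxon signed-rank)
#'
#' Pairwise one-sided signed-rank tests on paired per-window errors, with
#' Bonferroni correction over the number of unordered model pairs. The
#' winner is a model never significantly worse than any other; among such
#' models the one with the fewest parameters is chosen. With fewer than 6
#' paired samples the test is unreliable and the mean criterion is used
#' with a warning.
#'
#' @param errors windows x models matrix of paired error samples.
#' @param n_params parameter count per model.
#' @param alpha family-wise level before correction.
#' @return list with `winner` (column index), `worse` (logical matrix:
#'   `worse[i, j]` means model `i` is significantly worse than `j`),
#'   `p` (pairwise one-sided p-values, `p[i, j]` for "i better than j"),
#'   and `fallback` (TRUE when the mean criterion was used).
#' @export
median_best <- function(errors, n_params = NULL, alpha = 0.05) {
  errors <- as.matrix(errors)
  keep <- stats::complete.cases(errors)
  errors <- errors[keep, , drop = FALSE]
  m <- ncol(errors)
  n_params <- n_params %||% rep(0, m)
  if (nrow(errors) < 6L) {
    warnf("fewer than 6 paired samples; falling back to the mean criterion")
    mu <- colMeans(errors)
    best <- which(mu == min(mu))
    if (length(best) > 1L) best <- best[which.min(n_params[best])]
    return(list(winner = unname(best), worse = NULL, p = NULL,
                fallback = TRUE))
  }
  npairs <- m * (m - 1L) / 2L
  a_corr <- alpha / npairs
  p <- matrix(NA_real_, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    di <- errors[, i] - errors[, j]
    if (all(di == 0)) { p[i, j] <- 1; next }
    p[i, j] <- suppressWarnings(
      stats::wilcox.test(errors[, i], errors[, j], paired = TRUE,
                         alternative = "less")$p.value)
  }
  worse <- t(p) < a_corr            # worse[i, j]: j beats i significantly
  worse[is.na(worse)] <- FALSE
  never_worse <- which(rowSums(worse) == 0L)
  if (length(never_worse) == 0L) never_worse <- seq_len(m)
  winner <- never_worse[which.min(n_params[never_worse])]
  list(winner = winner, worse = worse, p = p, fallback = FALSE)
}

#' Statistical win rate over a lag grid
#'
#' For each channel, a lag order `L` "suffices" when its mean held-out MSE
#' is within two standard errors of the channel's best order:
#' `mse(L) <= mse(best) + 2 * sem(best)`. Returns the fraction of channels
#' for which each order suffices; the curve saturates at the smallest order
#' capturing the true dependence.
#'
#' @param mse_mean channels x orders matrix of mean MSE.
#' @param mse_sem channels x orders matrix of the standard error of the
#'   mean MSE (across test windows/folds).
#' @return numeric vector, one fraction per order.
#' @export
statistical_win_rate <- function(mse_mean, mse_sem) {
  mse_mean <- as.matrix(mse_mean); mse_sem <- as.matrix(mse_sem)
  if (anyNA(mse_sem) || any(!is.finite(mse_sem)))
    stopf("SEM undefined (single fold?)")
  frac <- numeric(ncol(mse_mean))
  for (ch in seq_len(nrow(mse_mean))) {
    b <- which.min(mse_mean[ch, ])
    ok <- mse_mean[ch, ] <= mse_mean[ch, b] + 2 * mse_sem[ch, b]
    frac <- frac + ok
  }
  frac / nrow(mse_mean)
}
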