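#' Model families
#'
#' The eight structural families of the one-step model. `a` is the
#' autoregressive block (always free), `b` the direct input block, `c` the
#' gated (switched / bilinear) interaction block, `d` the network block
#' (lagged history of other channels):
#' AR `{a}`, ARX `{a,b}`, VAR `{a,d}`, VARX `{a,b,d}`,
#' SL_AR `{a,c}`, SL_ARX `{a,b,c}`, SL_VAR `{a,c,d}`, SL_VARX `{a,b,c,d}`.
#' Switched-linear, amplitude-weighted and fully bilinear models share the
#' same free blocks and differ only in the gating series (see
#' [gating_signal]).
#' @export
MODEL_FAMILIES <- c("AR", "ARX", "VAR", "VARX",
                    "SL_AR", "SL_ARX", "SL_VAR", "SL_VARX")

family_blocks <- function(family) {
  family <- match.arg(family, MODEL_FAMILIES)
  list(has_b = family %in% c("ARX", "VARX", "SL_ARX", "SL_VARX"),
       has_c = grepl("^SL_", family),
       has_d = grepl("VAR", family))
}

#' Model specification
#'
#' Structural description of one channel model: which blocks are free, the
#' lag orders, the gating mode, the network source set, and (optionally) a
#' sparse delay-embedded autoregressive block with delay time `tau`.
#'
#' @param k target channel index.
#' @param L autoregressive lags (samples).
#' @param M input lags (samples).
#' @param P network lags (samples); used only by families with a `d` block.
#' @param family one of [MODEL_FAMILIES].
#' @param gating gating mode for the interaction block; `"none"` for linear
#'   families, one of `"switched"`, `"amplitude"`, `"bilinear"` for `SL_*`
#'   families (defaults to `"switched"`).
#' @param sources integer channel indices whose lagged history enters the
#'   network block; defaults to all channels except `k` at feature-building
#'   time when left `NULL`.
#' @param sparse logical; when `TRUE` the autoregressive block uses delayed
#'   lags `t - tau, t - 2 tau, ..., t - L tau` instead of `t - 1 ... t - L`.
#' @param tau delay time (samples, >= 1) for the sparse block.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(k = 1L, L = 1L, M = 0L, P = 0L,
                       family = "AR", gating = NULL,
                       sources = NULL, sparse = FALSE, tau = 1L) {
  family <- match.arg(family, MODEL_FAMILIES)
  blocks <- family_blocks(family)
  if (L < 0L || M < 0L || P < 0L) stopf("L, M, P must be >= 0")
  if (tau < 1L) stopf("tau must be >= 1")
  if (is.null(gating)) gating <- if (blocks$has_c) "switched" else "none"
  gating <- match.arg(gating, c("none", "switched", "amplitude", "bilinear"))
  if (blocks$has_c && gating == "none")
    stopf("family %s needs a gating mode", family)
  if (!blocks$has_c) gating <- "none"
  structure(
    list(k = as.integer(k), L = as.integer(L), M = as.integer(M),
         P = as.integer(P), family = family, gating = gating,
         sources = if (!is.null(sources)) as.integer(sources),
         sparse = isTRUE(sparse), tau = as.integer(tau)),
    class = "model_spec")
}

# Resolve the network source set against a channel count.
spec_sources <- function(spec, n_channels) {
  blocks <- family_blocks(spec$family)
  if (!blocks$has_d || spec$P == 0L) return(integer(0))
  src <- spec$sources %||% setdiff(seq_len(n_channels), spec$k)
  src <- setdiff(as.integer(src), spec$k)
  if (any(src < 1L | src > n_channels)) stopf("source index out of range")
  src
}

# Free-parameter count given a resolved source set.
spec_n_params <- function(spec, n_sources = NULL) {
  blocks <- family_blocks(spec$family)
  ns <- n_sources %||% length(spec$sources %||% integer(0))
  spec$L +
    (if (blocks$has_c) spec$L else 0L) +
    (if (blocks$has_b) spec$M else 0L) +
    (if (blocks$has_d) spec$P * ns else 0L)
}

# Largest backwards reach of the feature vector, in samples.
spec_max_lag <- function(spec) {
  aL <- if (spec$sparse) spec$L * spec$tau else spec$L
  max(aL, spec$M, spec$P, 1L)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "<model_spec> channel %d, family %s (L=%d, M=%d, P=%d, gating=%s%s)\n",
    x$k, x$family, x$L, x$M, x$P, x$gating,
    if (x$sparse) sprintf(", sparse tau=%d", x$tau) else ""))
  invisible(x)
}
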