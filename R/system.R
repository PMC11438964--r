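#' Sample a ground-truth switched / bilinear network system
#'
#' Draws a random parameter set for the one-step model
#' `dy_k(t) = (a_k + U(t) c_k)' y_k^L(t) + b_k' u^M(t) + sum_i d_ki' y_i^P(t)`
#' with guaranteed stability: each channel's STIM OFF regime (`a_k`) and
#' STIM ON regime (`a_k + c_k`) have companion spectral radius at most
#' `margin`, and the network coupling is globally rescaled until the full
#' multichannel system in both regimes is within `margin` as well.
#'
#' Autoregressive blocks are constructed from randomly placed characteristic
#' roots constrained to make the increment parameterization exact; input and
#' coupling magnitudes are drawn uniform with random sign. Blocks excluded by
#' the family are exactly zero.
#'
#' @param spec a [model_spec] giving the family, lags and gating mode.
#' @param geometry an [electrode_geometry]; its channel count sets `C`.
#' @param coupling_band optional `c(lo, hi)` distance interval (mm): network
#'   blocks `d_ki` are nonzero only for source-target pairs whose distance
#'   lies strictly inside the band. `NULL` couples all pairs.
#' @param source_set optional integer vector: only these channels may have
#'   outgoing network edges. Setting it to the anode plants the
#'   stimulation-site-centred spread structure probed by the distance
#'   profile analysis.
#' @param noise_sd innovation (process noise) standard deviation.
#' @param margin stability margin for the companion spectral radius (< 1).
#' @param b_range,d_range magnitude ranges for input and coupling weights.
#' @param a_override optional `L x C` matrix of autoregressive blocks to
#'   plant verbatim (rescaled toward zero root mass only if unstable beyond
#'   `margin`; an error is raised instead so planted structure is never
#'   silently altered).
#' @param b_override optional `M x C` matrix of input blocks to plant.
#' @param seed integer seed.
#' @return An object of class `ground_truth_system`.
#' @export
sample_ground_truth_system <- function(spec, geometry,
                                       coupling_band = NULL,
                                       source_set = NULL,
                                       noise_sd = 0.1,
                                       margin = 0.95,
                                       b_range = c(0.1, 0.4),
                                       d_range = c(0.05, 0.15),
                                       a_override = NULL,
                                       b_override = NULL,
                                       seed = 1L) {
  blocks <- family_blocks(spec$family)
  C <- geometry$n_channels
  L <- spec$L; M <- spec$M; P <- spec$P
  set.seed(child_seed(seed, "system"))

  a <- matrix(0, nrow = L, ncol = C)
  c_blk <- matrix(0, nrow = L, ncol = C)
  if (!is.null(a_override)) {
    a_override <- as.matrix(a_override)
    if (!all(dim(a_override) == c(L, C))) stopf("a_override must be L x C")
    a[] <- a_override
    for (k in seq_len(C))
      if (companion_radius(a[, k]) > margin + 1e-9)
        stopf("a_override channel %d exceeds stability margin", k)
  } else if (L > 0L) {
    for (k in seq_len(C)) a[, k] <- sample_stable_ar(L, margin)
  }
  if (blocks$has_c && L > 0L) {
    for (k in seq_len(C)) {
      a_on <- sample_stable_ar(L, margin)
      c_blk[, k] <- a_on - a[, k]
    }
  }

  b <- matrix(0, nrow = M, ncol = C)
  if (blocks$has_b && M > 0L) {
    if (!is.null(b_override)) {
      b_override <- as.matrix(b_override)
      if (!all(dim(b_override) == c(M, C))) stopf("b_override must be M x C")
      b[] <- b_override
    } else {
      b[] <- stats::runif(M * C, b_range[1], b_range[2]) *
        sample(c(-1, 1), M * C, replace = TRUE)
      # taper so the direct effect decays over the input history
      b <- b * exp(-outer(seq_len(M), rep(1, C)) / max(M, 1))
    }
  }

  d <- array(0, dim = c(C, C, max(P, 1L)))
  if (blocks$has_d && P > 0L && C > 1L) {
    dist <- geometry$pairwise_dist
    for (k in seq_len(C)) for (i in seq_len(C)) {
      if (i == k) next
      if (!is.null(source_set) && !(i %in% source_set)) next
      if (!is.null(coupling_band) &&
          !(dist[k, i] > coupling_band[1] && dist[k, i] < coupling_band[2]))
        next
      d[k, i, seq_len(P)] <- stats::runif(P, d_range[1], d_range[2]) *
        sample(c(-1, 1), P, replace = TRUE)
    }
    # global rescale until the coupled system is stable in both regimes
    ok <- FALSE
    for (it in 1:60) {
      r_off <- full_system_radius(a, d[, , seq_len(P), drop = FALSE])
      r_on <- full_system_radius(a + c_blk, d[, , seq_len(P), drop = FALSE])
      if (max(r_off, r_on) <= margin + 1e-9) { ok <- TRUE; break }
      d <- d * 0.8
    }
    if (!ok) stopf("could not stabilize coupled system within margin %.2f",
                   margin)
  }

  structure(
    list(a = a, b = b, c = c_blk, d = d,
         family = spec$family, gating = spec$gating,
         L = L, M = M, P = P, C = C,
         noise_sd = noise_sd, margin = margin,
         geometry = geometry, seed = as.integer(seed)),
    class = "ground_truth_system")
}

# Stable increment-form AR block of length L: place characteristic roots
# summing to exactly 1 (so the coefficient on y(t) is 1) inside the margin.
sample_stable_ar <- function(L, margin = 0.95, root_scale = 0.4) {
  for (it in 1:200) {
    r <- stats::runif(L, -root_scale, root_scale)
    last <- 1 - sum(r)
    if (abs(last) > margin) next
    cf <- Re(poly_from_roots(c(r, last)))
    a <- -cf[-(1:2)]
    if (length(a) == 0L) a <- numeric(0)
    if (companion_radius(a) <= margin + 1e-9) return(a)
  }
  stopf("could not sample a stable AR block of order %d", L)
}

# Spectral radius of the full coupled multichannel companion matrix for one
# regime (a: L x C autoregressive blocks, d: C x C x P coupling array).
full_system_radius <- function(a, d) {
  C <- ncol(a); L <- nrow(a); P <- dim(d)[3]
  lag <- max(L, P) + 1L
  A <- matrix(0, C * lag, C * lag)
  idx <- function(k, j) (k - 1L) * lag + j + 1L  # channel k, lag j (0-based)
  for (k in seq_len(C)) {
    A[idx(k, 0L), idx(k, 0L)] <- 1
    for (j in seq_len(L)) A[idx(k, 0L), idx(k, j)] <-
        A[idx(k, 0L), idx(k, j)] + a[j, k]
    for (i in seq_len(C)) for (j in seq_len(P))
      if (d[k, i, j] != 0) A[idx(k, 0L), idx(i, j)] <-
          A[idx(k, 0L), idx(i, j)] + d[k, i, j]
    for (j in seq_len(lag - 1L)) A[idx(k, j), idx(k, j - 1L)] <- 1
  }
  max(Mod(eigen(A, only.values = TRUE)$values))
}

# True parameter vector in the feature layout of build_features() for the
# channel of `spec`, restricted to the spec's source set.
theta_true <- function(system, spec) {
  blocks <- family_blocks(spec$family)
  k <- spec$k
  th <- system$a[seq_len(spec$L), k]
  if (blocks$has_c) th <- c(th, system$c[seq_len(spec$L), k])
  if (blocks$has_b) th <- c(th, system$b[seq_len(spec$M), k])
  if (blocks$has_d) {
    for (i in spec_sources(spec, system$C))
      th <- c(th, system$d[k, i, seq_len(spec$P)])
  }
  unname(th)
}

#' @export
print.ground_truth_system <- function(x, ...) {
  cat(sprintf(
    "<ground_truth_system> %s, C=%d, L=%d, M=%d, P=%d, noise_sd=%.3g\n",
    x$family, x$C, x$L, x$M, x$P, x$noise_sd))
  invisible(x)
}
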