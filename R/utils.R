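#' @keywords internal
"_PACKAGE"

# Coefficients of the monic polynomial with the given roots, highest degree
# first. Complex-safe; callers take Re() when roots come in conjugate pairs.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0i, p * ri)
  p
}

# Spectral radius of the one-step companion matrix of y(t+1) = y(t) +
# sum_j a_j y(t-j).  The coefficient on y(t) is structurally 1 because the
# model predicts the increment, not the level.
companion_radius <- function(a) {
  L <- length(a)
  if (L == 0L) return(1)
  Cm <- rbind(c(1, a), cbind(diag(L), rep(0, L)))
  max(Mod(eigen(Cm, only.values = TRUE)$values))
}

# Deterministic child seed for a named sub-stream, kept below 2^31.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) * 1103L + as.integer(h %% 100000L)) %% 2147483587L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
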