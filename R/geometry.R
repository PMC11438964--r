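#' Electrode geometry
#'
#' Container for per-channel 3-D electrode positions (mm), the identity of the
#' stimulated (anode) channel, and the full pairwise Euclidean distance matrix.
#'
#' @param coords numeric matrix, one row per channel, three columns (x, y, z)
#'   in millimetres.
#' @param anode_index integer channel index of the stimulation site.
#' @return An object of class `electrode_geometry` with fields `coords`,
#'   `anode_index`, `pairwise_dist` and `n_channels`.
#' @export
electrode_geometry <- function(coords, anode_index = 1L) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stopf("coords must be an n x 3 matrix")
  n <- nrow(coords)
  anode_index <- as.integer(anode_index)
  if (anode_index < 1L || anode_index > n) stopf("anode_index out of range")
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- NULL
  structure(
    list(coords = coords, anode_index = anode_index,
         pairwise_dist = d, n_channels = n),
    class = "electrode_geometry")
}

#' Sample a random electrode geometry
#'
#' Places `n_channels` electrodes uniformly in a cube of the given spatial
#' extent. Channel 1 is pinned at the origin and is the anode (stimulation
#' site), so that channel-to-anode distances are reproducible and span the
#' full extent.
#'
#' @param n_channels number of channels (>= 1).
#' @param extent_mm side length of the cube the electrodes occupy (mm).
#' @param seed integer seed; identical seeds give identical geometries.
#' @return An `electrode_geometry`.
#' @export
make_electrode_geometry <- function(n_channels, extent_mm = 100, seed = 1L) {
  if (n_channels < 1L) stopf("n_channels must be >= 1")
  if (extent_mm <= 0) stopf("extent_mm must be positive")
  rng <- local({ set.seed(child_seed(seed, "geometry")); NULL })
  coords <- matrix(stats::runif(3L * n_channels, 0, extent_mm),
                   ncol = 3L, byrow = TRUE)
  coords[1L, ] <- 0
  electrode_geometry(coords, anode_index = 1L)
}

#' @export
print.electrode_geometry <- function(x, ...) {
  cat(sprintf("<electrode_geometry> %d channels, anode = channel %d\n",
              x$n_channels, x$anode_index))
  invisible(x)
}
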