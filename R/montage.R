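#' Synthetic 64-channel EEG montage
#'
#' Quasi-uniform electrode layout on the upper hemisphere of a unit sphere
#' (Fibonacci lattice), with BioSemi-style channel labels A1--A32/B1--B32.
#' This is a synthetic stand-in for a manufacturer cap layout: spatial
#' relations (neighbourhoods, left/right symmetry of indices) are generic,
#' not anatomically calibrated.
#'
#' @param n_channels number of electrodes (default 64).
#' @return data.frame with columns `label`, `x`, `y`, `z` (3D unit sphere)
#'   and `px`, `py` (2D azimuthal-equidistant projection, vertex at origin).
#' @export
synthetic_montage <- function(n_channels = 64) {
  stopifnot(n_channels >= 2)
  i <- seq_len(n_channels)
  # upper hemisphere, avoid the rim (z from ~0.1 to ~1)
  z <- 1 - (i - 0.5) / n_channels * 0.9
  phi <- (i - 1) * pi * (3 - sqrt(5))  # golden angle
  r <- sqrt(pmax(0, 1 - z^2))
  x <- r * cos(phi)
  y <- r * sin(phi)
  half <- ceiling(n_channels / 2)
  label <- c(paste0("A", seq_len(half)),
             if (n_channels > half) paste0("B", seq_len(n_channels - half)))
  theta <- acos(pmin(1, pmax(-1, z)))  # polar angle from vertex
  data.frame(label = label, x = x, y = y, z = z,
             px = theta * cos(phi), py = theta * sin(phi),
             stringsAsFactors = FALSE)
}

#' Sensor adjacency graph from electrode positions
#'
#' Connects each pair of sensors whose 3D distance is below
#' `factor` times the median nearest-neighbour distance (the usual
#' distance-threshold neighbourhood definition for EEG caps).
#'
#' @param montage data.frame as returned by [synthetic_montage()].
#' @param factor threshold multiplier (default 1.4).
#' @return adjacency object: list with `ptr`/`adj` CSR vectors (0-based)
#'   and `n` points, as used by the cluster permutation tests.
#' @export
sensor_adjacency <- function(montage, factor = 1.4) {
  pos <- as.matrix(montage[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  thr <- factor * stats::median(nn)
  nb <- lapply(seq_len(nrow(pos)), function(i) which(d[i, ] < thr) - 1L)
  adjacency_from_neighbors(nb)
}

# Build CSR adjacency from a list of 0-based neighbour vectors.
adjacency_from_neighbors <- function(nb) {
  n <- length(nb)
  ptr <- c(0L, cumsum(vapply(nb, length, integer(1))))
  list(ptr = as.integer(ptr), adj = as.integer(unlist(nb)), n = n)
}

#' 1D chain adjacency (consecutive time points)
#' @param n number of points.
#' @return adjacency object (CSR), see [sensor_adjacency()].
#' @export
adjacency_1d <- function(n) {
  nb <- lapply(seq_len(n), function(i) {
    v <- c(i - 2L, i)  # 0-based neighbours i-1, i+1
    v[v >= 0L & v < n]
  })
  adjacency_from_neighbors(nb)
}

#' 2D grid adjacency with 4-connectivity
#'
#' Points are column-major flattened indices of an `nr` x `nc` grid, as
#' produced by `as.vector()` on an R matrix. Diagonal neighbours are not
#' connected, so two blobs touching only at a corner remain distinct.
#'
#' @param nr,nc grid dimensions.
#' @return adjacency object (CSR), see [sensor_adjacency()].
#' @export
adjacency_grid <- function(nr, nc) {
  nb <- vector("list", nr * nc)
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      id <- (j - 1L) * nr + i  # 1-based flat index
      v <- integer(0)
      if (i > 1) v <- c(v, id - 1L)
      if (i < nr) v <- c(v, id + 1L)
      if (j > 1) v <- c(v, id - nr)
      if (j < nc) v <- c(v, id + nr)
      nb[[id]] <- v - 1L
    }
  }
  adjacency_from_neighbors(nb)
}
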