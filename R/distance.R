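# Exact Euclidean distance transform on an anisotropic voxel grid.
#
# Felzenszwalb & Huttenlocher lower-envelope algorithm, applied separably
# along each axis with the axis's physical spacing, so distances come out in
# mm even when slices are thicker than the in-plane voxels.

# 1D squared-distance transform of f sampled at positions x (strictly
# increasing). Returns min_j f[j] + (x - x[j])^2 at each sample.
dt1d <- function(f, x) {
  n <- length(f)
  finite <- which(is.finite(f))
  if (length(finite) == 0L) return(f)
  v <- integer(n); zlo <- numeric(n + 1L)
  k <- 1L
  v[1L] <- finite[1L]
  zlo[1L] <- -Inf; zlo[2L] <- Inf
  if (length(finite) > 1L) {
    for (q in finite[-1L]) {
      repeat {
        p <- v[k]
        s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
        if (s <= zlo[k]) { k <- k - 1L } else break
      }
      k <- k + 1L
      v[k] <- q
      zlo[k] <- s
      zlo[k + 1L] <- Inf
    }
  }
  out <- numeric(n)
  k2 <- 1L
  for (q in seq_len(n)) {
    while (zlo[k2 + 1L] < x[q]) k2 <- k2 + 1L
    p <- v[k2]
    out[q] <- f[p] + (x[q] - x[p])^2
  }
  out
}

# Apply dt1d along one margin of a 3D array of squared distances.
dt_along <- function(arr, axis, h) {
  d <- dim(arr)
  x <- (seq_len(d[axis]) - 1) * h
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  for (j in seq_len(ncol(m))) m[, j] <- dt1d(m[, j], x)
  a <- array(m, dim = dim(a))
  aperm(a, order(perm))
}

#' Euclidean distance transform of a mask
#'
#' Exact distance in mm from every voxel to the nearest `TRUE` voxel centre
#' of `mask`, honouring anisotropic spacing. Voxels inside the mask have
#' distance 0.
#'
#' @param mask logical 3D array in (z, y, x) order
#' @param spacing voxel spacing (dz, dy, dx) in mm
#' @return numeric 3D array of distances in mm
#' @export
distance_transform <- function(mask, spacing) {
  if (!any(mask)) abort_geometry("distance transform of an empty mask")
  f <- array(Inf, dim = dim(mask))
  f[mask] <- 0
  f <- dt_along(f, 1L, spacing[1])
  f <- dt_along(f, 2L, spacing[2])
  f <- dt_along(f, 3L, spacing[3])
  sqrt(f)
}
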