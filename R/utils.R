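# small shared helpers: angle wrapping, grid indexing, connected components

#' Wrap angles into (-180, 180]
#'
#' @param deg numeric vector of angles in degrees.
#' @return angles wrapped to the interval (-180, 180].
#' @export
wrap_angle <- function(deg) {
  w <- (deg + 180) %% 360 - 180
  # map -180 to +180 so the interval is half-open on the left
  w[w == -180] <- 180
  w
}

#' Wrap angles into [0, 360)
#' @param deg numeric vector of angles in degrees.
#' @return angles in [0, 360).
#' @export
wrap_angle_360 <- function(deg) deg %% 360

# linear index <-> (i,j,k) for a 3D grid
lin_to_ijk <- function(idx, dim) arrayInd(idx, .dim = dim)
ijk_to_lin <- function(ijk, dim) {
  ijk <- matrix(ijk, ncol = 3)
  (ijk[, 3] - 1L) * dim[1] * dim[2] + (ijk[, 2] - 1L) * dim[1] + ijk[, 1]
}

# voxels of a sphere of given radius (in voxels) around a center, clipped to grid
sphere_voxels <- function(center, radius, dim) {
  r <- ceiling(radius)
  rng <- lapply(1:3, function(a) {
    seq(max(1L, floor(center[a] - r)), min(dim[a], ceiling(center[a] + r)))
  })
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  d2 <- (g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 + (g[, 3] - center[3])^2
  sort(ijk_to_lin(g[d2 <= radius^2 + 1e-9, , drop = FALSE], dim))
}

#' Connected components of a voxel set (6-neighbour face adjacency)
#'
#' @param voxels integer vector of linear voxel indices.
#' @param dim length-3 grid dimensions.
#' @return list of integer vectors, one per component, largest first.
#' @export
connected_components <- function(voxels, dim) {
  if (length(voxels) == 0) return(list())
  inset <- logical(prod(dim))
  inset[voxels] <- TRUE
  seen <- logical(prod(dim))
  comps <- list()
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (v in voxels) {
    if (seen[v]) next
    queue <- v
    seen[v] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      comp <- c(comp, cur)
      ijk <- lin_to_ijk(cur, dim)
      for (o in seq_len(6)) {
        nb <- ijk + offsets[o, ]
        if (any(nb < 1L) || any(nb > dim)) next
        nl <- ijk_to_lin(nb, dim)
        if (inset[nl] && !seen[nl]) {
          seen[nl] <- TRUE
          queue <- c(queue, nl)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(-vapply(comps, length, 1L))]
}

# center of mass in mm, origin at the volume center
com_mm <- function(voxels, dim, vox_mm) {
  ijk <- lin_to_ijk(voxels, dim)
  ctr <- (dim + 1) / 2
  colMeans((sweep(ijk, 2, ctr)) * vox_mm)
}

# contiguous runs of TRUE in a logical vector, as a 2-column matrix (start, end)
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
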