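#' Rasterize a centerline tree onto a voxel grid
#'
#' Every parent-child edge is sampled densely (at most half the minimum
#' spacing between consecutive samples) and each sample is mapped to its
#' nearest voxel, yielding a 26-connected voxel path per edge.
#'
#' @param tree an [airway_tree] whose node positions lie inside the grid.
#' @param grid an [image_grid].
#' @return Integer matrix (n x 3) of unique 1-based voxel indices, ordered
#'   by linear index.
#' @export
rasterize_centerline <- function(tree, grid) {
  if (nrow(tree) == 0L) stop("tree has no nodes")
  pos <- cbind(tree$x, tree$y, tree$z)
  ci <- world_to_index(grid, pos)
  ok <- in_grid(grid, ci)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("node %d at (%.3f, %.3f, %.3f) mm lies outside the grid",
                 tree$id[bad], tree$x[bad], tree$y[bad], tree$z[bad]))
  }
  step <- min(grid$spacing) / 2
  pts <- list(pos)
  idx <- stats::setNames(seq_len(nrow(tree)), as.character(tree$id))
  for (i in which(tree$parent != -1L)) {
    p <- idx[[as.character(tree$parent[i])]]
    a <- pos[p, ]
    b <- pos[i, ]
    len <- sqrt(sum((b - a)^2))
    ns <- max(1L, ceiling(len / step))
    if (ns > 1L) {
      t <- seq_len(ns - 1L) / ns
      pts[[length(pts) + 1L]] <- cbind(a[1] + t * (b[1] - a[1]),
                                       a[2] + t * (b[2] - a[2]),
                                       a[3] + t * (b[3] - a[3]))
    }
  }
  allp <- do.call(rbind, pts)
  vox <- world_to_voxel(grid, allp)
  lin <- linear_index(grid, vox)
  vox <- vox[!duplicated(lin), , drop = FALSE]
  vox[order(linear_index(grid, vox)), , drop = FALSE]
}

# squared Euclidean distance transform (mm^2) of a set of voxel indices;
# returns list(dist2 = 3-D array, nearest = linear index array of the
# closest site voxel)
distance_transform <- function(vox, grid) {
  mask <- array(FALSE, grid$dim)
  mask[cbind(vox[, 1], vox[, 2], vox[, 3])] <- TRUE
  r <- cpp_edt(as.vector(mask), grid$dim, grid$spacing)
  list(dist2 = array(r$dist2, grid$dim), nearest = array(r$nearest, grid$dim))
}

#' Ground-truth centerline probability map
#'
#' Builds the probability map used as the tracing target: the traced
#' centerline is rasterized, a Euclidean distance transform D(v) (mm,
#' anisotropy-aware, measured from voxel centers) is computed, and a
#' Gaussian weighting is applied:
#' \deqn{p(v) = \exp(-D(v)^2 / (2\sigma^2)).}
#' Probabilities are 1 exactly on centerline voxels and decrease strictly
#' with distance from the centerline, so points nearer the center of a
#' bronchus score higher.
#'
#' @param tree an [airway_tree] inside the grid.
#' @param grid an [image_grid].
#' @param sigma Gaussian scale in mm (> 0, default 1).
#' @return A [scalar_volume] with values in \[0, 1\].
#' @export
centerline_probability <- function(tree, grid, sigma = 1.0) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a positive number (mm)")
  vox <- rasterize_centerline(tree, grid)
  dt <- distance_transform(vox, grid)
  scalar_volume(exp(-dt$dist2 / (2 * sigma^2)), grid)
}
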