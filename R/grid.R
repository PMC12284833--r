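#' Voxel lattice geometry
#'
#' An `image_grid` records the geometry of a 3-D voxel lattice shared by all
#' volumes in a parcellation run: integer dimensions, physical spacing in mm
#' per voxel, and the world-space position (mm) of the centre of the first
#' voxel. Index convention is 1-based (R arrays); the centre of voxel
#' \code{(i,j,k)} sits at \code{origin + (c(i,j,k) - 1) * spacing}.
#'
#' @param dim integer vector of length 3, voxel counts per axis (all >= 1).
#' @param spacing numeric vector of length 3, mm per voxel (all > 0).
#' @param origin numeric vector of length 3, world position (mm) of the
#'   centre of voxel (1,1,1).
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(c(96, 96, 96), c(1, 1, 1))
#' index_to_world(g, c(1, 1, 1))
#' @export
image_grid <- function(dim, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(dim) != 3L || any(is.na(dim)) || any(dim < 1L))
    stop("`dim` must be 3 positive integers")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  structure(list(dim = dim, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm, origin (%.4g, %.4g, %.4g) mm\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$dim, b$dim) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Convert between voxel indices and world coordinates
#'
#' `index_to_world` maps (possibly fractional) 1-based voxel indices to world
#' mm; `world_to_index` is its inverse and returns fractional indices;
#' `world_to_voxel` rounds to the nearest voxel index.
#'
#' @param grid an [image_grid].
#' @param idx numeric matrix (n x 3) or length-3 vector of 1-based indices.
#' @param xyz numeric matrix (n x 3) or length-3 vector of world mm.
#' @return A matrix (n x 3), or a length-3 vector if the input was one.
#' @export
index_to_world <- function(grid, idx) {
  m <- to_mat3(idx)
  out <- sweep(sweep(m - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
  if (is.null(dim(idx))) out[1, ] else out
}

#' @rdname index_to_world
#' @export
world_to_index <- function(grid, xyz) {
  m <- to_mat3(xyz)
  out <- sweep(sweep(m, 2, grid$origin, "-"), 2, grid$spacing, "/") + 1
  if (is.null(dim(xyz))) out[1, ] else out
}

#' @rdname index_to_world
#' @export
world_to_voxel <- function(grid, xyz) {
  ci <- world_to_index(grid, xyz)
  m <- to_mat3(ci)
  out <- round(m)
  storage.mode(out) <- "integer"
  if (is.null(dim(xyz))) out[1, ] else out
}

to_mat3 <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3) else {
    stopifnot(ncol(x) == 3)
    matrix(as.numeric(x), ncol = 3)
  }
}

in_grid <- function(grid, ijk) {
  m <- to_mat3(ijk)
  m[, 1] >= 0.5 & m[, 1] < grid$dim[1] + 0.5 &
    m[, 2] >= 0.5 & m[, 2] < grid$dim[2] + 0.5 &
    m[, 3] >= 0.5 & m[, 3] < grid$dim[3] + 0.5
}

linear_index <- function(grid, ijk) {
  m <- to_mat3(ijk)
  as.integer((m[, 3] - 1) * grid$dim[1] * grid$dim[2] +
               (m[, 2] - 1) * grid$dim[1] + m[, 1])
}

#' Volumes on an image grid
#'
#' `scalar_volume` wraps a numeric 3-D array (e.g. a centerline probability
#' map or a geodesic arrival-time field); `label_volume` wraps an integer
#' array of region labels with 0 meaning background (used for lungs, lobes
#' and segment masks).
#'
#' @param data a 3-D array matching `grid$dim`.
#' @param grid an [image_grid].
#' @return An object of class `scalar_volume` or `label_volume` (both also
#'   class `lp_volume`), a list with elements `data` and `grid`.
#' @export
scalar_volume <- function(data, grid) {
  new_volume(data, grid, "scalar_volume", double = TRUE)
}

#' @rdname scalar_volume
#' @export
label_volume <- function(data, grid) {
  v <- new_volume(data, grid, "label_volume", double = FALSE)
  if (any(v$data < 0L, na.rm = TRUE)) stop("labels must be non-negative")
  v
}

new_volume <- function(data, grid, cls, double) {
  if (!inherits(grid, "image_grid")) stop("`grid` must be an image_grid")
  data <- as.array(data)
  if (length(dim(data)) != 3L || !all(dim(data) == grid$dim))
    stop("`data` dimensions do not match grid")
  storage.mode(data) <- if (double) "double" else "integer"
  structure(list(data = data, grid = grid), class = c(cls, "lp_volume"))
}

#' @export
print.lp_volume <- function(x, ...) {
  kind <- if (inherits(x, "label_volume")) "label_volume" else "scalar_volume"
  cat(sprintf("<%s> ", kind))
  print(x$grid)
  if (inherits(x, "label_volume")) {
    labs <- sort(unique(as.vector(x$data)))
    labs <- labs[labs != 0L]
    cat(sprintf("  labels: %s; background voxels: %d\n",
                if (length(labs)) paste(labs, collapse = ", ") else "(none)",
                sum(x$data == 0L)))
  } else {
    cat(sprintf("  range: [%.4g, %.4g]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

#' Read and write volumes as NIfTI
#'
#' Volumes are stored as NIfTI-1 with a diagonal affine built from the grid
#' (spacing on the diagonal, origin in the translation column). On reading,
#' the affine must be diagonal up to axis flips; oblique orientations are
#' rejected. Flipped axes are normalised to positive spacing by reversing
#' the data.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param kind `"scalar"` or `"label"`.
#' @param vol a `scalar_volume` or `label_volume`.
#' @return `read_volume` returns a volume; `write_volume` returns `path`
#'   invisibly.
#' @export
read_volume <- function(path, kind = c("scalar", "label")) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  if (any(abs(rot[row(rot) != col(rot)]) > 1e-4))
    stop("NIfTI affine of '", path, "' is not axis-aligned (oblique orientations unsupported)")
  dat <- as.array(img)
  if (length(dim(dat)) == 4L && dim(dat)[4] == 1L) dim(dat) <- dim(dat)[1:3]
  if (length(dim(dat)) != 3L) stop("'", path, "' is not a 3-D volume")
  spacing <- diag(rot)
  origin <- aff[1:3, 4]
  for (a in 1:3) {
    if (spacing[a] < 0) { # flip to positive spacing
      dat <- flip_axis(dat, a)
      origin[a] <- origin[a] + (dim(dat)[a] - 1) * spacing[a]
      spacing[a] <- -spacing[a]
    }
  }
  grid <- image_grid(dim(dat), spacing, origin)
  dat <- array(as.vector(as.numeric(dat)), dim(dat))  # drop NIfTI attributes
  if (kind == "label") label_volume(round(dat), grid) else scalar_volume(dat, grid)
}

flip_axis <- function(a, axis) {
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- dim(a)[axis]:1
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "lp_volume"))
  dat <- vol$data
  if (inherits(vol, "label_volume")) {
    storage.mode(dat) <- "integer"
  } else {
    storage.mode(dat) <- "double"
  }
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$grid$spacing
  aff <- rbind(cbind(diag(vol$grid$spacing), vol$grid$origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path,
                     datatype = if (inherits(vol, "label_volume")) "uint16" else "float")
  invisible(path)
}
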