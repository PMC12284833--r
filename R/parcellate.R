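#' Nearest-bronchus segment parcellation
#'
#' The core parcellation rule: every voxel of a lung lobe receives the label
#' of the nearest labeled segmental bronchus *of that lobe*,
#' \deqn{s(v) = \arg\min_k d_k(v),}
#' where \eqn{d_k(v)} is the Euclidean distance (mm) from the voxel center
#' to the labeled centerline of segment k — the whole propagated subtree
#' (tertiary branch plus downstream sub-branches), densely resampled along
#' its edges and rasterized to voxel centers. Background voxels of the lobe
#' mask stay background, segment labels never cross lobe boundaries, and
#' because segments nest inside lobes the candidate set per voxel never
#' exceeds five. Distance ties are broken towards the smallest segment
#' code.
#'
#' Implementation: one Euclidean distance transform per candidate segment
#' per lobe; this is required to agree voxel-for-voxel with the exhaustive
#' voxel-by-point scan (the test suite carries that oracle).
#'
#' @param lobes a [label_volume] of lobe codes (see [lobe_codes]).
#' @param tree a labeled [airway_tree] (after [propagate_labels]).
#' @param tax a [build_taxonomy()] object.
#' @return A [label_volume] of segment codes 1-18.
#' @export
nearest_bronchus_parcellation <- function(lobes, tree, tax = build_taxonomy()) {
  stopifnot(inherits(lobes, "label_volume"), inherits(tax, "segment_taxonomy"))
  grid <- lobes$grid
  pts <- labeled_centerline_points(tree, step = min(grid$spacing) / 2)
  if (nrow(pts) == 0L) stop("tree carries no segment labels")
  vox <- world_to_voxel(grid, as.matrix(pts[, c("x", "y", "z")]))
  ok <- in_grid(grid, vox)
  if (!all(ok)) stop("labeled centerline points fall outside the lobe grid")
  lcode <- lobe_codes(tax)
  out <- array(0L, grid$dim)
  lob_arr <- lobes$data
  for (lb in names(lcode)) {
    lin_lobe <- which(lob_arr == lcode[[lb]])
    if (!length(lin_lobe)) next
    cand <- segments_for_lobe(tax, lb)
    have <- cand[cand %in% unique(pts$label)]
    miss <- setdiff(cand, have)
    if (length(miss))
      warning(sprintf("lobe %s: no labeled bronchus for segment(s) %s",
                      lb, paste(miss, collapse = ", ")))
    if (!length(have))
      stop("lobe ", lb, " has voxels but no candidate bronchi")
    dmat <- matrix(Inf, length(lin_lobe), length(have))
    for (ci in seq_along(have)) {
      sv <- vox[pts$label == have[ci], , drop = FALSE]
      sv <- sv[!duplicated(linear_index(grid, sv)), , drop = FALSE]
      dt <- distance_transform(sv, grid)
      dmat[, ci] <- dt$dist2[lin_lobe]
    }
    # argmin with ties to the smallest code; `have` is ascending, and
    # max.col("first") on the negated distances picks the first minimum
    pick <- max.col(-dmat, ties.method = "first")
    out[lin_lobe] <- have[pick]
  }
  label_volume(out, grid)
}

#' Regularize a segment mask against a lobe mask
#'
#' Cleans an arbitrary segment label volume so it respects the lobe
#' hierarchy: (a) voxels outside the lungs (lobe 0) become background; (b)
#' in-lobe voxels carrying a segment that does not belong to that lobe, and
#' (c) in-lobe voxels left background, are reassigned to the nearest valid
#' in-lobe segment voxel (Euclidean mm, via the distance transform). A lobe
#' with no valid segment voxel at all falls back to its lowest-code segment
#' with a warning. The operation is idempotent.
#'
#' @param segments a [label_volume] of segment codes.
#' @param lobes a [label_volume] of lobe codes on the same grid.
#' @param tax a [build_taxonomy()] object.
#' @return A regularized [label_volume].
#' @export
regularize_by_lobes <- function(segments, lobes, tax = build_taxonomy()) {
  stopifnot(inherits(segments, "label_volume"), inherits(lobes, "label_volume"))
  if (!grids_equal(segments$grid, lobes$grid))
    stop("segment and lobe volumes are on different grids")
  grid <- segments$grid
  seg <- segments$data
  lob <- lobes$data
  out <- array(0L, grid$dim)
  lcode <- lobe_codes(tax)
  for (lb in names(lcode)) {
    lin_lobe <- which(lob == lcode[[lb]])
    if (!length(lin_lobe)) next
    cand <- segments_for_lobe(tax, lb)
    valid <- lin_lobe[seg[lin_lobe] %in% cand]
    if (!length(valid)) {
      warning("lobe ", lb, " contains no valid segment voxels; filling with segment ",
              min(cand))
      out[lin_lobe] <- min(cand)
      next
    }
    out[valid] <- seg[valid]
    fix <- setdiff(lin_lobe, valid)
    if (length(fix)) {
      sv <- arrayInd(valid, grid$dim)
      dt <- distance_transform(sv, grid)
      out[fix] <- seg[dt$nearest[fix]]
    }
  }
  label_volume(out, grid)
}

#' Thoracic landmarks
#'
#' The carina bifurcation and the sternum tips, in world mm; together they
#' anchor the region of interest that encompasses both lungs.
#'
#' @param carina,sternum_tips finite 3-vectors (mm).
#' @return An object of class `landmarks`.
#' @export
landmarks <- function(carina, sternum_tips) {
  carina <- as.numeric(carina)
  sternum_tips <- as.numeric(sternum_tips)
  if (length(carina) != 3L || any(!is.finite(carina)))
    stop("carina must be a finite 3-vector (mm)")
  if (length(sternum_tips) != 3L || any(!is.finite(sternum_tips)))
    stop("sternum_tips must be a finite 3-vector (mm)")
  structure(list(carina = carina, sternum_tips = sternum_tips),
            class = "landmarks")
}

#' Read/write landmarks as JSON
#'
#' Format: `{"carina": [x,y,z], "sternum_tips": [x,y,z]}`, world mm.
#'
#' @param path file path.
#' @param lm a [landmarks] object.
#' @export
read_landmarks <- function(path) {
  d <- jsonlite::fromJSON(path)
  if (!all(c("carina", "sternum_tips") %in% names(d)))
    stop("landmark JSON must contain 'carina' and 'sternum_tips': ", path)
  landmarks(d$carina, d$sternum_tips)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(lm, path) {
  jsonlite::write_json(list(carina = lm$carina, sternum_tips = lm$sternum_tips),
                       path, digits = NA)
  invisible(path)
}

#' Crop around landmarks and resample to isotropic spacing
#'
#' Builds the axis-aligned box spanned by the two landmarks, expands it by a
#' per-axis margin on each side, clips it to the volume, and resamples the
#' cropped region to isotropic `out_spacing` (trilinear interpolation for
#' scalar volumes, nearest neighbor for label volumes, so label resampling
#' can never invent labels). When the clipped box covers the whole volume
#' and `out_spacing` equals the input spacing the output is voxel-identical
#' to the input.
#'
#' @param volume a [scalar_volume] or [label_volume].
#' @param lm a [landmarks] object; both landmarks must lie inside the
#'   volume.
#' @param out_spacing isotropic output spacing in mm (default 2).
#' @param margin_mm per-axis margin added on each side of the landmark box,
#'   default `c(150, 100, 150)` mm (lateral, antero-posterior,
#'   cranio-caudal).
#' @return A volume of the same kind on the new grid.
#' @export
crop_resample <- function(volume, lm, out_spacing = 2.0,
                          margin_mm = c(150, 100, 150)) {
  stopifnot(inherits(volume, "lp_volume"), inherits(lm, "landmarks"))
  grid <- volume$grid
  for (p in list(lm$carina, lm$sternum_tips))
    if (!in_grid(grid, world_to_index(grid, p)))
      stop(sprintf("landmark (%.1f, %.1f, %.1f) mm lies outside the volume",
                   p[1], p[2], p[3]))
  margin_mm <- rep_len(as.numeric(margin_mm), 3L)
  lo <- pmin(lm$carina, lm$sternum_tips) - margin_mm
  hi <- pmax(lm$carina, lm$sternum_tips) + margin_mm
  # clip to the voxel-center extent and snap to input voxel centers
  lo_idx <- pmax(ceiling(world_to_index(grid, lo) - 1e-9), 1)
  hi_idx <- pmin(floor(world_to_index(grid, hi) + 1e-9), grid$dim)
  lo_w <- index_to_world(grid, lo_idx)
  hi_w <- index_to_world(grid, hi_idx)
  out_dim <- pmax(1L, as.integer(floor((hi_w - lo_w) / out_spacing + 1e-9)) + 1L)
  out_grid <- image_grid(out_dim, rep(out_spacing, 3), lo_w)
  # output voxel centers mapped to continuous input indices
  gx <- lo_w[1] + (seq_len(out_dim[1]) - 1) * out_spacing
  gy <- lo_w[2] + (seq_len(out_dim[2]) - 1) * out_spacing
  gz <- lo_w[3] + (seq_len(out_dim[3]) - 1) * out_spacing
  cix <- (gx - grid$origin[1]) / grid$spacing[1] + 1
  ciy <- (gy - grid$origin[2]) / grid$spacing[2] + 1
  ciz <- (gz - grid$origin[3]) / grid$spacing[3] + 1
  if (inherits(volume, "label_volume")) {
    ix <- pmin(pmax(round(cix), 1L), grid$dim[1])
    iy <- pmin(pmax(round(ciy), 1L), grid$dim[2])
    iz <- pmin(pmax(round(ciz), 1L), grid$dim[3])
    out <- volume$data[ix, iy, iz, drop = FALSE]
    dim(out) <- out_dim
    label_volume(out, out_grid)
  } else {
    out <- resample_trilinear(volume$data, cix, ciy, ciz)
    scalar_volume(out, out_grid)
  }
}

# separable gather for trilinear resampling on an axis-aligned grid
resample_trilinear <- function(arr, cix, ciy, ciz) {
  d <- dim(arr)
  cl <- function(ci, n) pmin(pmax(ci, 1), n)
  cix <- cl(cix, d[1]); ciy <- cl(ciy, d[2]); ciz <- cl(ciz, d[3])
  x0 <- pmax(pmin(floor(cix), d[1] - 1), 1); fx <- cix - x0
  y0 <- pmax(pmin(floor(ciy), d[2] - 1), 1); fy <- ciy - y0
  z0 <- pmax(pmin(floor(ciz), d[3] - 1), 1); fz <- ciz - z0
  if (d[1] == 1L) { x0 <- rep(1, length(cix)); fx <- rep(0, length(cix)) }
  if (d[2] == 1L) { y0 <- rep(1, length(ciy)); fy <- rep(0, length(ciy)) }
  if (d[3] == 1L) { z0 <- rep(1, length(ciz)); fz <- rep(0, length(ciz)) }
  nx <- length(cix); ny <- length(ciy); nz <- length(ciz)
  out <- array(0, c(nx, ny, nz))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx) fx else 1 - fx
    wy <- if (dy) fy else 1 - fy
    wz <- if (dz) fz else 1 - fz
    sub <- arr[pmin(x0 + dx, d[1]), pmin(y0 + dy, d[2]), pmin(z0 + dz, d[3]),
               drop = FALSE]
    dim(sub) <- c(nx, ny, nz)
    w <- array(outer(outer(wx, wy), wz), c(nx, ny, nz))
    out <- out + w * sub
  }
  out
}
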