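#' Synthetic thoracic phantom specification
#'
#' Parameters for the phantom generator. The defaults produce a 96 x 96 x
#' 96 voxel, 1 mm isotropic thorax with two ellipsoidal lungs and a
#' branching airway tree carrying the anatomical segment counts (3/2/5/4/4
#' tertiary bronchi across RUL/RML/RLL/LUL/LLL). All randomness (direction
#' and length jitter) flows from `seed` in a fixed traversal order, so an
#' identical spec yields bit-identical outputs.
#'
#' @param seed integer RNG seed.
#' @param dim,spacing,origin grid geometry (defaults 96^3, 1 mm, 0).
#' @param lung_semiaxes_mm list with `right` and `left` ellipsoid semi-axes
#'   (mm).
#' @param branch_angle_deg c(mean, jitter) branching angle from the parent
#'   direction for segmental/sub-segmental children.
#' @param branch_length_mm list of c(mean, jitter) lengths per generation:
#'   `lobar`, `segmental`, `subsegmental`.
#' @param sigma_mm Gaussian scale of the probability map (mm).
#' @param node_step_mm spacing of centerline nodes along branches (mm).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 42L,
                         dim = c(96L, 96L, 96L),
                         spacing = c(1, 1, 1),
                         origin = c(0, 0, 0),
                         lung_semiaxes_mm = list(right = c(17, 22, 30),
                                                 left = c(17, 22, 30)),
                         branch_angle_deg = c(40, 10),
                         branch_length_mm = list(lobar = c(14, 2),
                                                 segmental = c(16, 3),
                                                 subsegmental = c(10, 2)),
                         sigma_mm = 1.0,
                         node_step_mm = 2.0) {
  structure(list(seed = as.integer(seed),
                 grid = image_grid(dim, spacing, origin),
                 lung_semiaxes_mm = lung_semiaxes_mm,
                 branch_angle_deg = branch_angle_deg,
                 branch_length_mm = branch_length_mm,
                 sigma_mm = sigma_mm,
                 node_step_mm = node_step_mm),
            class = "phantom_spec")
}

# unit vector helpers
unit <- function(v) v / sqrt(sum(v^2))
ortho_basis <- function(w) {
  w <- unit(w)
  a <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(pracma_cross(w, a))
  v <- pracma_cross(w, u)
  list(u = u, v = v, w = w)
}
pracma_cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                                 a[3] * b[1] - a[1] * b[3],
                                 a[1] * b[2] - a[2] * b[1])

#' Generate a synthetic thoracic phantom
#'
#' Builds, deterministically from the spec seed: (1) two ellipsoidal lung
#' masks; (2) an airway centerline tree — trachea descending to the carina,
#' one main bronchus per lung, 3+2 lobar branches steered towards lobe
#' anchor regions, segmental children with the anatomical 3/2/5/4/4 counts,
#' and one further sub-segmental generation; (3) lobe masks by
#' nearest-lobar-subtree assignment within each lung; (4) single-point
#' annotations on the first node of each segmental branch; (5) propagated
#' segment labels; (6) the centerline probability map; and (7) ground-truth
#' segment masks via an exhaustive voxel-by-point scan that is fully
#' independent of the production parcellation, so the two can cross-check
#' each other.
#'
#' @param spec a [phantom_spec].
#' @return An object of class `phantom_bundle`: list with `lungs`, `lobes`,
#'   `tree` (labeled), `annotations`, `prob`, `segments_gt`, `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  # the sampled geometry occasionally violates a bundle invariant (branch
  # boxed in, subtrees too close); redraw deterministically from a derived
  # seed until it does not
  last <- NULL
  for (attempt in seq_len(25L)) {
    bundle <- tryCatch(
      build_phantom_once(spec, (spec$seed + (attempt - 1L) * 1000003L) %% .Machine$integer.max),
      error = function(e) e)
    if (!inherits(bundle, "error")) return(bundle)
    if (!grepl("phantom", conditionMessage(bundle))) stop(bundle)
    last <- bundle
  }
  stop(last)
}

build_phantom_once <- function(spec, seed) {
  grid <- spec$grid
  tax <- build_taxonomy()
  set.seed(seed)

  extent <- grid$origin + (grid$dim - 1) * grid$spacing
  ctr <- (grid$origin + extent) / 2
  lung_ctr <- list(right = c(grid$origin[1] + 0.29 * (extent[1] - grid$origin[1]),
                             ctr[2], ctr[3] - 0.06 * (extent[3] - grid$origin[3])),
                   left = c(grid$origin[1] + 0.71 * (extent[1] - grid$origin[1]),
                            ctr[2], ctr[3] - 0.06 * (extent[3] - grid$origin[3])))
  semi <- spec$lung_semiaxes_mm
  inside_lung <- function(p, side, margin = 2) {
    c0 <- lung_ctr[[side]]
    a <- pmax(semi[[side]] - margin, 1)
    sum(((p - c0) / a)^2) <= 1
  }

  nodes <- list()
  nid <- 0L
  add_chain <- function(from, dir, len, step, parent_id) {
    force(parent_id)
    ns <- max(2L, ceiling(len / step))
    ids <- integer(ns)
    for (s in seq_len(ns)) {
      nid <<- nid + 1L
      p <- from + dir * (len * s / ns)
      nodes[[nid]] <<- c(id = nid, x = p[1], y = p[2], z = p[3],
                         parent = parent_id)
      ids[s] <- nid
      parent_id <- nid
    }
    ids
  }
  jitter_dir <- function(base, angle_mean, angle_jit, azimuth) {
    th <- (angle_mean + stats::runif(1, -angle_jit, angle_jit)) * pi / 180
    ph <- azimuth + stats::runif(1, -0.3, 0.3)
    b <- ortho_basis(base)
    unit(cos(th) * b$w + sin(th) * (cos(ph) * b$u + sin(ph) * b$v))
  }
  # intra-lung branches already placed, tagged by (lobe, segment) so new
  # branches can keep clear of other lobes' and other segments' subtrees;
  # points are stored densely (0.5 mm) so clearance holds along whole edges
  placed_pts <- list()
  clearance_mm <- 2.5   # > voxel diagonal + sampling slack: no shared voxels
  exempt_mm <- 6.0      # siblings legitimately share the branch-point area
  avoid_points <- function(from, lobe, seg) {
    out <- list()
    for (e in placed_pts) {
      same_lobe <- e$lobe == lobe
      same_seg <- same_lobe && !is.na(e$seg) && !is.na(seg) && e$seg == seg
      if (same_seg || (same_lobe && is.na(e$seg) && is.na(seg))) next
      if (same_lobe && (is.na(e$seg) || is.na(seg)) && !same_seg) {
        # segmental vs own lobar chain (or vice versa): related, skip
        if (is.na(seg) != is.na(e$seg)) next
      }
      pts <- e$pts
      # sibling structures (same lung hilum / same lobar end) are allowed
      # near the shared origin: exempt same-lobe points, and other-lobe
      # points only for lobar branches (which all start at the hilum)
      if (same_lobe || is.na(seg)) {
        d0 <- sqrt(rowSums(sweep(pts, 2, from)^2))
        pts <- pts[d0 > exempt_mm, , drop = FALSE]
      }
      if (nrow(pts)) out[[length(out) + 1L]] <- pts
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }
  # a child branch that must stay inside the lung and clear of unrelated
  # subtrees; jitter is redrawn up to 50 times, bending progressively
  # towards the lung center and shortening, before giving up
  add_lung_branch <- function(from, base_dir, len_spec, angle_spec, azimuth,
                              side, parent_id, step, lobe, seg = NA_integer_) {
    avoid <- avoid_points(from, lobe, seg)
    for (att in seq_len(50L)) {
      dir <- jitter_dir(base_dir, angle_spec[1], angle_spec[2], azimuth)
      if (att > 10L)
        dir <- unit(dir + 0.05 * (att - 10L) * unit(lung_ctr[[side]] - from))
      len <- max(step, len_spec[1] + stats::runif(1, -len_spec[2], len_spec[2]))
      if (att > 25L) len <- max(step, len * (1 - 0.02 * (att - 25L)))
      nfine <- max(2L, ceiling(len / 0.5))
      tt <- seq_len(nfine) / nfine
      samp <- cbind(from[1] + tt * len * dir[1], from[2] + tt * len * dir[2],
                    from[3] + tt * len * dir[3])
      ns <- max(2L, ceiling(len / step))
      ok <- all(vapply(seq_len(ns), function(s)
        inside_lung(from + dir * (len * s / ns), side), logical(1)))
      if (ok && !is.null(avoid)) {
        d2 <- outer(rowSums(samp^2), rowSums(avoid^2), "+") -
          2 * samp %*% t(avoid)
        ok <- min(d2) > clearance_mm^2
      }
      if (ok) {
        placed_pts[[length(placed_pts) + 1L]] <<-
          list(pts = samp, lobe = lobe, seg = seg)
        return(list(ids = add_chain(from, dir, len, step, parent_id),
                    dir = dir))
      }
    }
    stop("phantom branch escapes the lung mask after 50 attempts; ",
         "use larger lung semi-axes or shorter branch lengths")
  }

  step <- spec$node_step_mm
  # trachea: top of the volume down to the carina
  top <- c(ctr[1], ctr[2], grid$origin[3] + 0.92 * (extent[3] - grid$origin[3]))
  carina <- c(ctr[1], ctr[2], ctr[3] + 0.18 * (extent[3] - grid$origin[3]))
  nid <- nid + 1L
  nodes[[nid]] <- c(id = nid, x = top[1], y = top[2], z = top[3], parent = -1L)
  tr_ids <- add_chain(top, unit(carina - top), sqrt(sum((carina - top)^2)),
                      step, nid)
  carina_id <- tr_ids[length(tr_ids)]
  carina_pos <- carina

  # per-lobe anchor points the lobar branches steer towards (fractions of
  # each lung's semi-axes)
  anchor <- function(side, f) lung_ctr[[side]] + f * semi[[side]]
  lobe_anchor <- list(RUL = anchor("right", c(-0.10, -0.10, 0.55)),
                      RML = anchor("right", c(-0.20, -0.50, 0.05)),
                      RLL = anchor("right", c(-0.10, 0.30, -0.50)),
                      LUL = anchor("left", c(0.10, -0.15, 0.55)),
                      LLL = anchor("left", c(0.05, 0.25, -0.50)))
  lobe_side <- c(RUL = "right", RML = "right", RLL = "right",
                 LUL = "left", LLL = "left")
  seg_codes_by_lobe <- lapply(stats::setNames(tax$lobes, tax$lobes),
                              function(lb) segments_for_lobe(tax, lb))

  ann_node <- integer(0)
  ann_code <- integer(0)
  lobar_subtree_first <- stats::setNames(integer(5), tax$lobes)
  lobar_subtree_last <- stats::setNames(integer(5), tax$lobes)
  angle <- spec$branch_angle_deg
  lens <- spec$branch_length_mm

  for (side in c("right", "left")) {
    # main bronchus: from the carina towards the upper hilum of the lung
    hilum_target <- lung_ctr[[side]] + c(0, 0, 0.45 * semi[[side]][3])
    hdir <- unit(hilum_target - carina_pos)
    hlen <- 0.62 * sqrt(sum((hilum_target - carina_pos)^2))
    main_ids <- add_chain(carina_pos, hdir, hlen, step, carina_id)
    hilum_id <- main_ids[length(main_ids)]
    hilum_pos <- carina_pos + hdir * hlen
    lobes_here <- names(lobe_side)[lobe_side == side]
    for (lb in lobes_here) {
      first_node_of_lobe <- nid + 1L
      # lobar branch: steered at the lobe anchor with mild jitter
      ldir_base <- unit(lobe_anchor[[lb]] - hilum_pos)
      lb_res <- add_lung_branch(hilum_pos, ldir_base, lens$lobar,
                                c(8, 6), 0, side, hilum_id, step, lobe = lb)
      lob_end_id <- lb_res$ids[length(lb_res$ids)]
      lob_end_pos <- c(nodes[[lob_end_id]][["x"]], nodes[[lob_end_id]][["y"]],
                       nodes[[lob_end_id]][["z"]])
      codes <- seg_codes_by_lobe[[lb]]
      nseg <- length(codes)
      for (ci in seq_len(nseg)) {
        az <- 2 * pi * (ci - 1) / nseg
        sg <- add_lung_branch(lob_end_pos, lb_res$dir, lens$segmental,
                              angle, az, side, lob_end_id, step,
                              lobe = lb, seg = codes[ci])
        ann_node <- c(ann_node, sg$ids[1L])
        ann_code <- c(ann_code, codes[ci])
        seg_end_id <- sg$ids[length(sg$ids)]
        seg_end_pos <- c(nodes[[seg_end_id]][["x"]], nodes[[seg_end_id]][["y"]],
                         nodes[[seg_end_id]][["z"]])
        for (si in 1:2) {
          add_lung_branch(seg_end_pos, sg$dir, lens$subsegmental,
                          c(angle[1] - 5, angle[2]), pi * (si - 1) + pi / 4,
                          side, seg_end_id, step, lobe = lb, seg = codes[ci])
        }
      }
      lobar_subtree_first[lb] <- first_node_of_lobe
      lobar_subtree_last[lb] <- nid
    }
  }

  nm <- do.call(rbind, nodes)
  tree <- airway_tree(data.frame(id = as.integer(nm[, "id"]), x = nm[, "x"],
                                 y = nm[, "y"], z = nm[, "z"],
                                 parent = as.integer(nm[, "parent"])))

  # lung masks: voxel centers inside either ellipsoid
  wx <- grid$origin[1] + (seq_len(grid$dim[1]) - 1) * grid$spacing[1]
  wy <- grid$origin[2] + (seq_len(grid$dim[2]) - 1) * grid$spacing[2]
  wz <- grid$origin[3] + (seq_len(grid$dim[3]) - 1) * grid$spacing[3]
  ellipsoid_mask <- function(side) {
    c0 <- lung_ctr[[side]]; a <- semi[[side]]
    qx <- ((wx - c0[1]) / a[1])^2
    qy <- ((wy - c0[2]) / a[2])^2
    qz <- ((wz - c0[3]) / a[3])^2
    outer(outer(qx, qy, "+"), qz, "+") <= 1
  }
  rmask <- ellipsoid_mask("right")
  lmask <- ellipsoid_mask("left")
  lungs_arr <- array(0L, grid$dim)
  lungs_arr[rmask] <- 1L
  lungs_arr[lmask & !rmask] <- 2L
  lungs <- label_volume(lungs_arr, grid)

  # lobes: nearest lobar subtree within each lung (ties to the smaller
  # lobe code), using the same rasterized argmin machinery one level up
  lcode <- lobe_codes(tax)
  lobes_arr <- array(0L, grid$dim)
  subtree_vox <- lapply(tax$lobes, function(lb) {
    rows <- lobar_subtree_first[lb]:lobar_subtree_last[lb]
    sub <- tree[tree$id %in% rows, , drop = FALSE]
    rasterize_centerline_rows(sub, tree, grid)
  })
  names(subtree_vox) <- tax$lobes
  for (side in c("right", "left")) {
    lung_lab <- if (side == "right") 1L else 2L
    lin <- which(lungs_arr == lung_lab)
    if (!length(lin)) next
    lobes_here <- names(lobe_side)[lobe_side == side]
    dmat <- matrix(Inf, length(lin), length(lobes_here))
    for (ci in seq_along(lobes_here)) {
      dt <- distance_transform(subtree_vox[[lobes_here[ci]]], grid)
      dmat[, ci] <- dt$dist2[lin]
    }
    pick <- max.col(-dmat, ties.method = "first")
    lobes_arr[lin] <- lcode[lobes_here][pick]
  }
  lobes <- label_volume(lobes_arr, grid)

  ann <- segmental_annotation(ann_node, ann_code)
  tree <- propagate_labels(tree, ann)
  prob <- centerline_probability(tree, grid, sigma = spec$sigma_mm)

  # ground truth by exhaustive voxel-by-point scan (independent of the
  # EDT-based production parcellation)
  segments_gt <- exhaustive_parcellation(lobes, tree, tax)

  bundle <- structure(list(lungs = lungs, lobes = lobes, tree = tree,
                           annotations = ann, prob = prob,
                           segments_gt = segments_gt, spec = spec),
                      class = "phantom_bundle")
  check_phantom_bundle(bundle, tax)
  bundle
}

# rasterize the edges of a subtree (rows of `tree` restricted to `sub`),
# including the edge down from the subtree's entry node's parent position
rasterize_centerline_rows <- function(sub, tree, grid) {
  sub2 <- sub
  # re-root the subtree at its first node so rasterize_centerline accepts it
  entry <- !(sub2$parent %in% sub2$id)
  sub2$parent[entry] <- -1L
  if (sum(entry) != 1L) stop("subtree is not a single rooted component")
  rasterize_centerline(airway_tree(sub2), grid)
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat("<phantom_bundle>\n  ")
  print(x$lungs$grid)
  cat(sprintf("  tree: %d nodes, %d branch points, %.0f mm total length\n",
              nrow(x$tree), count_branch_points(x$tree), tree_length(x$tree)))
  cat(sprintf("  segments in ground truth: %d\n",
              length(setdiff(unique(as.vector(x$segments_gt$data)), 0L))))
  invisible(x)
}

# exhaustive (voxel x labeled-point) nearest-bronchus scan; the slow,
# obviously-correct counterpart of nearest_bronchus_parcellation
exhaustive_parcellation <- function(lobes, tree, tax = build_taxonomy()) {
  grid <- lobes$grid
  pts <- labeled_centerline_points(tree, step = min(grid$spacing) / 2)
  vox <- world_to_voxel(grid, as.matrix(pts[, c("x", "y", "z")]))
  keep <- !duplicated(cbind(linear_index(grid, vox), pts$label))
  vox <- vox[keep, , drop = FALSE]
  lab <- pts$label[keep]
  ctr <- index_to_world(grid, vox)   # distances to rasterized voxel centers
  out <- array(0L, grid$dim)
  lcode <- lobe_codes(tax)
  for (lb in names(lcode)) {
    lin <- which(lobes$data == lcode[[lb]])
    if (!length(lin)) next
    cand <- segments_for_lobe(tax, lb)
    cand <- cand[cand %in% lab]
    if (!length(cand)) stop("lobe ", lb, " has voxels but no candidate bronchi")
    vpos <- index_to_world(grid, arrayInd(lin, grid$dim))
    best_d <- rep(Inf, length(lin))
    best_k <- rep(0L, length(lin))
    for (k in cand) {               # ascending codes: ties keep the first
      pk <- ctr[lab == k, , drop = FALSE]
      d2 <- rep(Inf, length(lin))
      chunk <- 400L
      for (s in seq(1L, nrow(pk), by = chunk)) {
        e <- min(s + chunk - 1L, nrow(pk))
        blk <- pk[s:e, , drop = FALSE]
        dd <- outer(rowSums(vpos^2), rowSums(blk^2), "+") -
          2 * vpos %*% t(blk)
        d2 <- pmin(d2, dd[cbind(seq_len(nrow(dd)),
                                max.col(-dd, ties.method = "first"))])
      }
      upd <- d2 < best_d
      best_d[upd] <- d2[upd]
      best_k[upd] <- k
    }
    out[lin] <- best_k
  }
  label_volume(out, grid)
}

check_phantom_bundle <- function(bundle, tax = build_taxonomy()) {
  cands <- segmental_candidates(bundle$tree)
  if (length(cands) != 18L)
    stop("phantom has ", length(cands), " generation-3 branches, expected 18")
  first_labels <- vapply(cands, function(b)
    bundle$tree$label[match(b$node_ids[1L], bundle$tree$id)], integer(1))
  per_lobe <- table(factor(lobe_of(tax, first_labels), levels = tax$lobes))
  want <- c(RUL = 3L, RML = 2L, RLL = 5L, LUL = 4L, LLL = 4L)
  if (!all(per_lobe[names(want)] == want))
    stop("phantom segmental branches are not partitioned 3/2/5/4/4 by lobe")
  lab_nodes <- bundle$tree[!is.na(bundle$tree$label), ]
  vox <- world_to_voxel(bundle$lobes$grid,
                        cbind(lab_nodes$x, lab_nodes$y, lab_nodes$z))
  lobe_at <- bundle$lobes$data[vox]
  lcode <- lobe_codes(tax)
  want_lobe <- lcode[lobe_of(tax, lab_nodes$label)]
  if (!all(lobe_at == want_lobe))
    stop("phantom labeled node(s) fall outside their own lobe mask; ",
         "use larger lung semi-axes or shorter branch lengths")
  # no voxel may carry labeled points of two different segments: a shared
  # voxel ties the argmin and breaks the inclusion-rate = 1 self-consistency
  grid <- bundle$lobes$grid
  pts <- labeled_centerline_points(bundle$tree, min(grid$spacing) / 2)
  pvox <- world_to_voxel(grid, as.matrix(pts[, c("x", "y", "z")]))
  pair <- unique(data.frame(lin = linear_index(grid, pvox), lab = pts$label))
  if (anyDuplicated(pair$lin))
    stop("phantom segments share a rasterized centerline voxel; ",
         "use larger lung semi-axes or shorter branch lengths")
  invisible(bundle)
}

#' Inject a gap into a probability map
#'
#' Zeroes the probability in a slab of thickness `gap_mm` perpendicular to
#' a branch at its arc-length midpoint (laterally limited to `radius_mm`
#' around the midpoint), emulating a locally failed centerline prediction.
#' Used to exercise the tracer's gap-bridging behavior.
#'
#' @param prob a [scalar_volume].
#' @param tree the generating [airway_tree].
#' @param branch_index index into [branch_decomposition] of `tree`.
#' @param gap_mm slab thickness (0 returns the input unchanged); must be
#'   shorter than the branch.
#' @param radius_mm lateral extent of the slab (default 6).
#' @return The modified [scalar_volume].
#' @export
inject_gap <- function(prob, tree, branch_index, gap_mm, radius_mm = 6) {
  stopifnot(inherits(prob, "scalar_volume"))
  br <- branch_decomposition(tree)
  if (branch_index < 1L || branch_index > length(br))
    stop("branch_index out of range (tree has ", length(br), " branches)")
  if (gap_mm == 0) return(prob)
  ids <- br[[branch_index]]$node_ids
  rows <- match(ids, tree$id)
  p <- cbind(tree$x[rows], tree$y[rows], tree$z[rows])
  seglen <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  total <- sum(seglen)
  if (gap_mm >= total)
    stop(sprintf("gap (%.1f mm) must be shorter than the branch (%.1f mm)",
                 gap_mm, total))
  cum <- c(0, cumsum(seglen))
  half <- total / 2
  si <- max(which(cum <= half))
  si <- min(si, nrow(p) - 1L)
  t <- (half - cum[si]) / seglen[si]
  mid <- p[si, ] + t * (p[si + 1L, ] - p[si, ])
  u <- unit(p[si + 1L, ] - p[si, ])
  grid <- prob$grid
  wx <- grid$origin[1] + (seq_len(grid$dim[1]) - 1) * grid$spacing[1]
  wy <- grid$origin[2] + (seq_len(grid$dim[2]) - 1) * grid$spacing[2]
  wz <- grid$origin[3] + (seq_len(grid$dim[3]) - 1) * grid$spacing[3]
  dx <- outer(outer(wx - mid[1], rep(0, grid$dim[2]), "+"),
              rep(0, grid$dim[3]), "+")
  dy <- outer(outer(rep(0, grid$dim[1]), wy - mid[2], "+"),
              rep(0, grid$dim[3]), "+")
  dz <- outer(outer(rep(0, grid$dim[1]), rep(0, grid$dim[2]), "+"),
              wz - mid[3], "+")
  axial <- dx * u[1] + dy * u[2] + dz * u[3]
  lat2 <- dx^2 + dy^2 + dz^2 - axial^2
  slab <- abs(axial) <= gap_mm / 2 & lat2 <= radius_mm^2
  out <- prob$data
  out[slab] <- 0
  scalar_volume(out, grid)
}
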