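#' Tracer parameters
#'
#' Tuning constants for the geodesic backtracking tracer. `prob_threshold`
#' gates the foreground; `speed_floor` keeps the marching speed strictly
#' positive so the front can cross small gaps in the probability map;
#' `coverage_fraction` stops the branch loop once that fraction of the
#' foreground lies within `coverage_radius_mm` of the traced centerline;
#' `step_mm` is the backtracking step (default half the minimum spacing,
#' resolved at trace time); traces shorter than `min_branch_nodes` nodes are
#' discarded as noise.
#'
#' @param prob_threshold foreground gate in (0,1), default 0.05.
#' @param speed_floor positive marching-speed floor, default 1e-4.
#' @param coverage_fraction stop target in (0,1], default 0.98.
#' @param coverage_radius_mm coverage radius in mm, default 2.
#' @param step_mm backtracking step in mm, or `NULL` for half the minimum
#'   grid spacing.
#' @param min_branch_nodes minimum nodes per kept trace, default 3.
#' @return An object of class `tracer_params`.
#' @export
tracer_params <- function(prob_threshold = 0.05, speed_floor = 1e-4,
                          coverage_fraction = 0.98, coverage_radius_mm = 2.0,
                          step_mm = NULL, min_branch_nodes = 3L) {
  chk <- function(x, lo, hi, name, lo_open = TRUE, hi_open = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        (if (lo_open) x <= lo else x < lo) ||
        (if (hi_open) x >= hi else x > hi))
      stop(name, " out of range")
  }
  chk(prob_threshold, 0, 1, "prob_threshold")
  chk(speed_floor, 0, Inf, "speed_floor")
  chk(coverage_fraction, 0, 1, "coverage_fraction", hi_open = FALSE)
  chk(coverage_radius_mm, 0, Inf, "coverage_radius_mm")
  if (!is.null(step_mm)) chk(step_mm, 0, Inf, "step_mm")
  if (min_branch_nodes < 1L) stop("min_branch_nodes out of range")
  structure(list(prob_threshold = prob_threshold, speed_floor = speed_floor,
                 coverage_fraction = coverage_fraction,
                 coverage_radius_mm = coverage_radius_mm, step_mm = step_mm,
                 min_branch_nodes = as.integer(min_branch_nodes)),
            class = "tracer_params")
}

#' Geodesic arrival time from a seed voxel
#'
#' Solves the eikonal equation |grad T| F = 1 by first-order upwind fast
#' marching with speed `F(v) = max(prob(v), speed_floor)`. The floor keeps
#' every voxel reachable, which is what lets the tracer bridge small gaps of
#' zeroed probability instead of producing disconnected trees.
#'
#' @param prob a [scalar_volume] with values in \[0, 1\].
#' @param seed 1-based voxel index `c(i, j, k)`.
#' @param params a [tracer_params].
#' @return A [scalar_volume] of arrival times (T(seed) = 0).
#' @export
geodesic_time <- function(prob, seed, params = tracer_params()) {
  stopifnot(inherits(prob, "scalar_volume"))
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > prob$grid$dim))
    stop("seed voxel out of bounds: (", paste(seed, collapse = ", "), ")")
  speed <- pmax(as.vector(prob$data), params$speed_floor)
  lin <- linear_index(prob$grid, matrix(seed, ncol = 3))
  tvec <- cpp_fast_march(speed, prob$grid$dim, prob$grid$spacing, lin)
  scalar_volume(array(tvec, prob$grid$dim), prob$grid)
}


# foreground voxels whose arrival time is >= that of every foreground
# 26-neighbor: the geodesic endpoints the backtracker starts from
local_time_maxima <- function(tarr, fg, grid) {
  d <- grid$dim
  tmasked <- array(-Inf, d)
  tmasked[fg] <- tarr[fg]
  ok <- array(TRUE, d)
  src_rng <- function(n, by) if (by == 1L) 1:(n - 1) else 2:n
  dst_rng <- function(n, by) if (by == 1L) 2:n else 1:(n - 1)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sh <- array(-Inf, d)
    sx <- if (dx == 0) 1:d[1] else src_rng(d[1], dx)
    dxi <- if (dx == 0) 1:d[1] else dst_rng(d[1], dx)
    sy <- if (dy == 0) 1:d[2] else src_rng(d[2], dy)
    dyi <- if (dy == 0) 1:d[2] else dst_rng(d[2], dy)
    sz <- if (dz == 0) 1:d[3] else src_rng(d[3], dz)
    dzi <- if (dz == 0) 1:d[3] else dst_rng(d[3], dz)
    sh[dxi, dyi, dzi] <- tmasked[sx, sy, sz]
    ok <- ok & (tmasked >= sh)
  }
  ok & array(fg, d)
}

# trilinear interpolation of a 3-D array at a continuous 1-based index
trilinear_at <- function(arr, ci) {
  d <- dim(arr)
  ci <- pmin(pmax(ci, 1), d)  # clamp to the sampled domain
  i0 <- pmax(pmin(floor(ci), d - 1), 1)
  f <- ci - i0
  i0 <- as.integer(i0)
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) *
      (if (dy) f[2] else 1 - f[2]) *
      (if (dz) f[3] else 1 - f[3])
    if (w > 0) v <- v + w * arr[i0[1] + dx, i0[2] + dy, i0[3] + dz]
  }
  v
}

#' Trace a centerline tree from a probability map
#'
#' Iterative backtracking in the style of the Rivulet neuron tracer:
#' foreground voxels are those with probability at or above the threshold;
#' geodesic arrival times T are marched from the seed (by default the
#' highest-probability voxel); then, repeatedly, the uncovered foreground
#' voxel with the largest T is backtracked along -grad T in sub-voxel steps
#' until it reaches covered territory or the seed, the path becomes a chain
#' of tree nodes attached to the nearest existing node, and foreground
#' voxels near the path are marked covered. Paths shorter than
#' `min_branch_nodes` are discarded (their surroundings still count as
#' covered, which keeps the loop finite on noisy maps). The loop ends when
#' the covered fraction reaches `coverage_fraction` or no uncovered
#' foreground remains. The result is always a single-rooted valid tree.
#'
#' @param prob a [scalar_volume] probability map.
#' @param params a [tracer_params].
#' @param seed optional 1-based voxel index of the root; default is the
#'   foreground voxel with maximal probability (ties: lowest linear index).
#' @return An [airway_tree] rooted at the seed.
#' @export
trace <- function(prob, params = tracer_params(), seed = NULL) {
  stopifnot(inherits(prob, "scalar_volume"))
  grid <- prob$grid
  pv <- as.vector(prob$data)
  fg <- pv >= params$prob_threshold
  if (!any(fg)) stop("no foreground above threshold")
  if (is.null(seed)) {
    best <- which(fg)[which.max(pv[fg])]
    seed <- arrayInd(best, grid$dim)[1, ]
  } else {
    seed <- as.integer(seed)
    if (length(seed) != 3L || any(seed < 1L) || any(seed > grid$dim))
      stop("seed voxel out of bounds")
  }
  step <- if (is.null(params$step_mm)) min(grid$spacing) / 2 else params$step_mm
  tvol <- geodesic_time(prob, seed, params)
  tarr <- tvol$data
  tvec <- as.vector(tarr)

  fg_idx <- which(fg)
  # candidate backtracking origins: geodesic endpoints, i.e. foreground
  # voxels whose arrival time is a local maximum within their foreground
  # 26-neighborhood (true branch termini; tube fringe and junction pockets
  # always have a higher-T foreground neighbor further downstream)
  lmax <- local_time_maxima(tarr, fg, grid)
  fg_idx <- fg_idx  # kept for coverage bookkeeping
  covered <- logical(prod(grid$dim))
  seed_pos <- index_to_world(grid, seed)
  # root node at the seed voxel center
  nodes_x <- seed_pos[1]; nodes_y <- seed_pos[2]; nodes_z <- seed_pos[3]
  nodes_parent <- -1L
  n_nodes <- 1L
  # radius estimate: distance to the nearest background (sub-threshold) voxel
  bg_idx <- which(!fg)
  rad_arr <- if (length(bg_idx)) {
    bg_vox <- arrayInd(bg_idx, grid$dim)
    sqrt(distance_transform(bg_vox, grid)$dist2)
  } else array(0, grid$dim)
  # coverage erasure scales with the local tube radius (Rivulet-style), so
  # a traced centerline retires its whole tube, not just a fixed-radius core
  erase_radius <- function(pvox)
    pmax(params$coverage_radius_mm, rad_arr[pvox])
  seed_vox <- matrix(seed, ncol = 3)
  covered <- cpp_cover_points(covered, matrix(seed_pos, ncol = 3),
                              erase_radius(seed_vox), grid$dim,
                              grid$spacing, grid$origin)

  parr <- prob$data
  recenter <- function(x) {
    # nudge towards the probability ridge (the tube axis) so the traced
    # path stays centered and its erasure retires the full cross-section
    h <- pmax(grid$spacing / 2, 1e-6)
    gp <- numeric(3)
    for (a in 1:3) {
      e <- c(0, 0, 0); e[a] <- h[a]
      gp[a] <- (trilinear_at(parr, world_to_index(grid, x + e)) -
                  trilinear_at(parr, world_to_index(grid, x - e))) / (2 * h[a])
    }
    gn <- sqrt(sum(gp^2))
    if (is.finite(gn) && gn > 1e-9) x + 0.5 * step * gp / gn else x
  }

  descend <- function(start_vox) {
    x <- index_to_world(grid, start_vox)
    budget <- max(20L, ceiling(10 * sqrt(sum((x - seed_pos)^2)) / step))
    path <- matrix(x, ncol = 3)
    t_prev <- trilinear_at(tarr, world_to_index(grid, x))
    for (s in seq_len(budget)) {
      ci <- world_to_index(grid, x)
      vox <- pmin(pmax(round(ci), 1L), grid$dim)
      if (s > 1L) {
        # touch-down on the existing tree: stop once an existing node is
        # within one step, so proximal branch pieces are actually traversed
        # rather than bridged by a long connection edge
        dmin <- min((nodes_x - x[1])^2 + (nodes_y - x[2])^2 +
                      (nodes_z - x[3])^2)
        if (dmin <= step^2) return(list(path = path, status = "node"))
      }
      if (sqrt(sum((x - seed_pos)^2)) <= step)
        return(list(path = path, status = "seed"))
      h <- pmax(grid$spacing / 2, 1e-6)
      g <- numeric(3)
      for (a in 1:3) {
        e <- c(0, 0, 0); e[a] <- h[a]
        g[a] <- (trilinear_at(tarr, world_to_index(grid, x + e)) -
                   trilinear_at(tarr, world_to_index(grid, x - e))) / (2 * h[a])
      }
      gn <- sqrt(sum(g^2))
      moved <- FALSE
      if (is.finite(gn) && gn > 1e-12) {
        xn <- x - step * g / gn
        tn <- trilinear_at(tarr, world_to_index(grid, xn))
        if (is.finite(tn) && tn < t_prev - 1e-12) {
          x <- recenter(xn)
          t_prev <- trilinear_at(tarr, world_to_index(grid, x))
          moved <- TRUE
        }
      }
      if (!moved) {
        # escape flat/noisy spots: hop to the lowest-T voxel in the
        # 26-neighborhood of the current voxel
        nb <- as.matrix(expand.grid(i = -1:1, j = -1:1, k = -1:1))
        nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
        cand <- sweep(nb, 2, vox, "+")
        ok <- cand[, 1] >= 1 & cand[, 1] <= grid$dim[1] &
          cand[, 2] >= 1 & cand[, 2] <= grid$dim[2] &
          cand[, 3] >= 1 & cand[, 3] <= grid$dim[3]
        cand <- cand[ok, , drop = FALSE]
        tc <- tvec[linear_index(grid, cand)]
        b <- which.min(tc)
        if (!length(b) || !is.finite(tc[b]) || tc[b] >= t_prev - 1e-12)
          return(list(path = path, status = "stuck"))
        x <- index_to_world(grid, cand[b, ])
        t_prev <- tc[b]
      }
      path <- rbind(path, x)
    }
    list(path = path, status = "budget")
  }

  lmax_idx <- fg_idx[lmax[fg_idx]]
  repeat {
    unc <- fg_idx[!covered[fg_idx]]
    if (!length(unc)) break
    if ((1 - length(unc) / length(fg_idx)) >= params$coverage_fraction) break
    cand <- lmax_idx[!covered[lmax_idx]]
    if (!length(cand)) break
    origin_lin <- cand[which.max(tvec[cand])]
    origin_vox <- arrayInd(origin_lin, grid$dim)[1, ]
    res <- descend(origin_vox)
    path <- res$path
    # coverage state of each path point *before* this path marks its own
    # territory; paths that mostly revisit covered ground are noise twigs
    pvox <- world_to_voxel(grid, path)
    pvox[, 1] <- pmin(pmax(pvox[, 1], 1L), grid$dim[1])
    pvox[, 2] <- pmin(pmax(pvox[, 2], 1L), grid$dim[2])
    pvox[, 3] <- pmin(pmax(pvox[, 3], 1L), grid$dim[3])
    was_covered <- covered[linear_index(grid, pvox)]
    covered <- cpp_cover_points(covered, path, erase_radius(pvox),
                                grid$dim, grid$spacing, grid$origin)
    covered[origin_lin] <- TRUE
    n_new <- sum(!was_covered)
    keep <- res$status %in% c("node", "seed") &&
      n_new >= params$min_branch_nodes
    if (!keep) next
    # junction zones breed leftover pockets between diverging tubes; retire
    # a wider ball around the attachment end of every kept path
    tailn <- max(1L, nrow(path) - 5L)
    covered <- cpp_cover_points(covered,
                                path[tailn:nrow(path), , drop = FALSE],
                                erase_radius(pvox[tailn:nrow(path), ,
                                                  drop = FALSE]) + 1.0,
                                grid$dim, grid$spacing, grid$origin)
    # attach: proximal end of the path links to the nearest existing node
    prox <- path[nrow(path), ]
    d2 <- (nodes_x - prox[1])^2 + (nodes_y - prox[2])^2 + (nodes_z - prox[3])^2
    parent <- which.min(d2)
    for (r in rev(seq_len(nrow(path)))) {
      n_nodes <- n_nodes + 1L
      nodes_x[n_nodes] <- path[r, 1]
      nodes_y[n_nodes] <- path[r, 2]
      nodes_z[n_nodes] <- path[r, 3]
      nodes_parent[n_nodes] <- parent
      parent <- n_nodes
    }
  }

  vox <- world_to_voxel(grid, cbind(nodes_x, nodes_y, nodes_z))
  vox[, 1] <- pmin(pmax(vox[, 1], 1L), grid$dim[1])
  vox[, 2] <- pmin(pmax(vox[, 2], 1L), grid$dim[2])
  vox[, 3] <- pmin(pmax(vox[, 3], 1L), grid$dim[3])
  radii <- rad_arr[vox]
  airway_tree(data.frame(id = seq_len(n_nodes), x = nodes_x, y = nodes_y,
                         z = nodes_z, radius = radii,
                         parent = nodes_parent))
}

#' Length-weighted centerline recovery
#'
#' Samples the reference tree's edges at a fine step and reports the
#' fraction of sampled centerline length lying within `tol_mm` of any node
#' of the traced tree. Used to quantify how much of the true airway
#' centerline a trace recovered.
#'
#' @param truth reference [airway_tree].
#' @param traced traced [airway_tree].
#' @param tol_mm distance tolerance in mm (default 1.5).
#' @param sample_mm sampling step along reference edges (default 0.25 mm).
#' @return Fraction in \[0, 1\].
#' @export
tree_recovery_fraction <- function(truth, traced, tol_mm = 1.5, sample_mm = 0.25) {
  idx <- stats::setNames(seq_len(nrow(truth)), as.character(truth$id))
  samples <- list()
  for (i in which(truth$parent != -1L)) {
    p <- idx[[as.character(truth$parent[i])]]
    a <- c(truth$x[p], truth$y[p], truth$z[p])
    b <- c(truth$x[i], truth$y[i], truth$z[i])
    len <- sqrt(sum((b - a)^2))
    ns <- max(2L, ceiling(len / sample_mm) + 1L)
    t <- seq(0, 1, length.out = ns)
    w <- rep(len / ns, ns)
    samples[[length(samples) + 1L]] <-
      cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
            a[3] + t * (b[3] - a[3]), w)
  }
  if (!length(samples)) return(NA_real_)
  sm <- do.call(rbind, samples)
  tp <- cbind(traced$x, traced$y, traced$z)
  tol2 <- tol_mm^2
  hit <- logical(nrow(sm))
  # chunked nearest-point check to bound memory
  chunk <- 2000L
  for (s in seq(1L, nrow(sm), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(sm))
    block <- sm[s:e, 1:3, drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(tp^2), "+") - 2 * block %*% t(tp)
    hit[s:e] <- apply(d2, 1, min) <= tol2 + 1e-9
  }
  sum(sm[hit, 4]) / sum(sm[, 4])
}
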