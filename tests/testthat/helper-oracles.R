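# Brute-force oracles and small synthetic fixtures. Everything here is
# deliberately slow and obvious so it can stand as an independent check of
# the package's distance-transform / parcellation / metric code paths.

# all voxel centers of a grid, world mm (n x 3)
oracle_voxel_centers <- function(grid) {
  idx <- arrayInd(seq_len(prod(grid$dim)), grid$dim)
  sweep(sweep(idx - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

# exhaustive Euclidean distance (mm) from every voxel center to the nearest
# of a set of voxel indices
oracle_distance <- function(vox, grid) {
  q <- oracle_voxel_centers(grid)
  p <- sweep(sweep(vox - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
  d2 <- outer(rowSums(q^2), rowSums(p^2), "+") - 2 * q %*% t(p)
  array(sqrt(pmax(apply(d2, 1, min), 0)), grid$dim)
}

# exhaustive nearest-bronchus parcellation: scans every (voxel, rasterized
# labeled point) pair per lobe; ties to the smallest segment code
oracle_parcellation <- function(lobes, tree, tax = build_taxonomy()) {
  grid <- lobes$grid
  pts <- lungparc:::labeled_centerline_points(tree, min(grid$spacing) / 2)
  vox <- world_to_voxel(grid, as.matrix(pts[, c("x", "y", "z")]))
  ctr <- index_to_world(grid, vox)
  lab <- pts$label
  out <- array(0L, grid$dim)
  lcode <- lobe_codes(tax)
  for (lb in names(lcode)) {
    lin <- which(lobes$data == lcode[[lb]])
    if (!length(lin)) next
    cand <- sort(intersect(segments_for_lobe(tax, lb), unique(lab)))
    vpos <- index_to_world(grid, arrayInd(lin, grid$dim))
    best_d <- rep(Inf, length(lin))
    best_k <- rep(0L, length(lin))
    for (k in cand) {
      pk <- unique(ctr[lab == k, , drop = FALSE])
      for (r in seq_len(nrow(pk))) {
        d2 <- (vpos[, 1] - pk[r, 1])^2 + (vpos[, 2] - pk[r, 2])^2 +
          (vpos[, 3] - pk[r, 3])^2
        upd <- d2 < best_d
        best_d[upd] <- d2[upd]
        best_k[upd] <- k
      }
    }
    out[lin] <- best_k
  }
  label_volume(out, grid)
}

# all-pairs symmetric surface distances, 6-connectivity surface with volume
# borders counting as surface
oracle_surface_distances <- function(maskA, maskB, spacing = c(1, 1, 1)) {
  surf <- function(mask) {
    d <- dim(mask)
    keep <- which(mask)
    idx <- arrayInd(keep, d)
    on_surface <- logical(length(keep))
    for (r in seq_along(keep)) {
      v <- idx[r, ]
      if (any(v == 1L) || any(v == d)) { on_surface[r] <- TRUE; next }
      for (a in 1:3) for (s in c(-1L, 1L)) {
        w <- v; w[a] <- w[a] + s
        if (!mask[w[1], w[2], w[3]]) on_surface[r] <- TRUE
      }
    }
    idx[on_surface, , drop = FALSE]
  }
  sa <- surf(maskA)
  sb <- surf(maskB)
  mm <- function(i) sweep(i - 1, 2, spacing, "*")
  pa <- mm(sa); pb <- mm(sb)
  cross <- function(p, q) {
    d2 <- outer(rowSums(p^2), rowSums(q^2), "+") - 2 * p %*% t(q)
    sqrt(pmax(apply(d2, 1, min), 0))
  }
  d_ab <- cross(pa, pb)
  d_ba <- cross(pb, pa)
  list(d_ab = d_ab, d_ba = d_ba, pooled = c(d_ab, d_ba))
}

# direct membership count for the gap slab
oracle_gap_count <- function(prob_before, tree, branch_index, gap_mm,
                             radius_mm = 6) {
  br <- branch_decomposition(tree)
  ids <- br[[branch_index]]$node_ids
  rows <- match(ids, tree$id)
  p <- cbind(tree$x[rows], tree$y[rows], tree$z[rows])
  seglen <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  half <- sum(seglen) / 2
  si <- min(max(which(cum <= half)), nrow(p) - 1L)
  t <- (half - cum[si]) / seglen[si]
  mid <- p[si, ] + t * (p[si + 1L, ] - p[si, ])
  u <- (p[si + 1L, ] - p[si, ]) / sqrt(sum((p[si + 1L, ] - p[si, ])^2))
  grid <- prob_before$grid
  ctr <- oracle_voxel_centers(grid)
  rel <- sweep(ctr, 2, mid)
  ax <- rel %*% u
  lat2 <- rowSums(rel^2) - ax^2
  sum(abs(ax) <= gap_mm / 2 & lat2 <= radius_mm^2 & as.vector(prob_before$data) > 0)
}

# Small random "two-lobe" phantom: ellipsoidal lobe masks plus labeled
# centerline chains, for parcellation oracle-equivalence checks.
make_mini_phantom <- function(seed, dim_range = 32:64) {
  set.seed(seed)
  tax <- build_taxonomy()
  d <- sample(dim_range, 3, replace = TRUE)
  grid <- image_grid(d, c(1, 1, 1))
  ext <- d - 1
  lobe_ids <- sort(sample(tax$lobes, 2))
  lcode <- lobe_codes(tax)
  centers <- list(c(0.28 * ext[1], 0.5 * ext[2], 0.5 * ext[3]),
                  c(0.72 * ext[1], 0.5 * ext[2], 0.5 * ext[3]))
  semi <- pmax(ext / 5, 4)
  arr <- array(0L, d)
  wx <- seq_len(d[1]) - 1; wy <- seq_len(d[2]) - 1; wz <- seq_len(d[3]) - 1
  for (i in 1:2) {
    c0 <- centers[[i]]
    q <- outer(outer(((wx - c0[1]) / semi[1])^2, ((wy - c0[2]) / semi[2])^2, "+"),
               ((wz - c0[3]) / semi[3])^2, "+")
    arr[q <= 1 & arr == 0L] <- lcode[[lobe_ids[i]]]
  }
  lobes <- label_volume(arr, grid)
  # labeled chains: a root plus, per lobe, chains for 2-3 of its segments
  nodes <- data.frame(id = 1L, x = ext[1] / 2, y = ext[2] / 2, z = ext[3] - 1,
                      parent = -1L, label = NA_integer_)
  nid <- 1L
  for (i in 1:2) {
    codes <- segments_for_lobe(tax, lobe_ids[i])
    codes <- sort(sample(codes, sample(2:min(3, length(codes)), 1)))
    for (k in codes) {
      start <- centers[[i]] + stats::runif(3, -0.3, 0.3) * semi
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      nsteps <- sample(4:8, 1)
      parent <- 1L
      for (s in seq_len(nsteps)) {
        p <- start + dir * 1.5 * (s - 1)
        p <- pmin(pmax(p, 1), ext - 1)  # stay inside the grid
        nid <- nid + 1L
        nodes <- rbind(nodes, data.frame(id = nid, x = p[1], y = p[2],
                                         z = p[3], parent = parent,
                                         label = k))
        parent <- nid
      }
    }
  }
  list(lobes = lobes, tree = airway_tree(nodes), grid = grid)
}

# 26-connectivity check for a set of voxel indices forming a path
is_26_connected <- function(vox) {
  n <- nrow(vox)
  if (n <= 1L) return(TRUE)
  visited <- logical(n)
  visited[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- integer(0)
    for (f in frontier) {
      adj <- which(!visited &
                     abs(vox[, 1] - vox[f, 1]) <= 1L &
                     abs(vox[, 2] - vox[f, 2]) <= 1L &
                     abs(vox[, 3] - vox[f, 3]) <= 1L)
      visited[adj] <- TRUE
      nxt <- c(nxt, adj)
    }
    frontier <- nxt
  }
  all(visited)
}
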