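#' Dice overlap for one segment
#'
#' \eqn{2|A_k \cap B_k| / (|A_k| + |B_k|)} between the voxel sets carrying
#' code `k` in the two label volumes. `NA` (missing) when both sets are
#' empty.
#'
#' @param A,B [label_volume]s on the same grid.
#' @param k segment code.
#' @return Dice coefficient in \[0, 1\], or `NA`.
#' @export
dice <- function(A, B, k) {
  stopifnot(inherits(A, "label_volume"), inherits(B, "label_volume"))
  if (!grids_equal(A$grid, B$grid)) stop("volumes are on different grids")
  a <- A$data == k
  b <- B$data == k
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(NA_real_)
  2 * sum(a & b) / (na + nb)
}

# surface voxels of a logical mask: members with >= 1 face neighbor (6-
# connectivity) outside the mask, or sitting on the volume border
surface_mask <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  if (!any(mask)) return(out)
  shift <- function(m, axis, by) {
    r <- array(FALSE, d)  # outside treated as background
    src <- dst <- lapply(d, seq_len)
    n <- d[axis]
    if (by == 1L) { dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1) }
    else { dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
    r[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    r
  }
  interior <- mask
  for (axis in 1:3) {
    if (d[axis] == 1L) { interior[] <- FALSE; next }
    interior <- interior & shift(mask, axis, 1L) & shift(mask, axis, -1L)
  }
  mask & !interior
}

#' Symmetric surface distances between two masks
#'
#' Surface voxels are mask members with at least one 6-connected face
#' neighbor outside the mask (volume-border voxels count as surface).
#' Returns the pooled symmetric multiset of distances — from every surface
#' voxel of A to the nearest surface voxel of B and vice versa, in mm —
#' from which HD95 (95th percentile, linear interpolation of order
#' statistics) and ASSD (mean) are derived.
#'
#' @param maskA,maskB logical 3-D arrays of equal dimensions (non-empty).
#' @param spacing voxel spacing in mm (length 3).
#' @return List with `d_ab`, `d_ba`, `pooled` (numeric vectors, mm),
#'   `hd95`, `assd`.
#' @export
surface_distances <- function(maskA, maskB, spacing = c(1, 1, 1)) {
  if (!any(maskA) || !any(maskB)) stop("surface distances need two non-empty sets")
  stopifnot(all(dim(maskA) == dim(maskB)))
  grid <- image_grid(dim(maskA), spacing)
  sa <- which(surface_mask(maskA))
  sb <- which(surface_mask(maskB))
  va <- arrayInd(sa, grid$dim)
  vb <- arrayInd(sb, grid$dim)
  dta <- distance_transform(va, grid)
  dtb <- distance_transform(vb, grid)
  d_ab <- sqrt(dtb$dist2[sa])  # A-surface -> nearest B-surface
  d_ba <- sqrt(dta$dist2[sb])
  pooled <- c(d_ab, d_ba)
  list(d_ab = d_ab, d_ba = d_ba, pooled = pooled,
       hd95 = stats::quantile(pooled, 0.95, type = 7, names = FALSE),
       assd = mean(pooled))
}

#' Bronchial inclusion rate for one segment
#'
#' The fraction of segment k's detected bronchial centerline points that
#' the predicted parcellation covers with the correct segment. Points are
#' the labeled nodes plus dense samples along labeled edges (as in the
#' parcellation). The primary denominator counts only points falling on
#' non-background predicted voxels, so gross lung under-segmentation is
#' reported separately rather than silently deflating the rate; the
#' all-points variant is also returned.
#'
#' @param pred predicted segment [label_volume].
#' @param tree labeled [airway_tree].
#' @param k segment code.
#' @return List with `rate` (in-lung denominator; `NA` when no labeled-k
#'   point lies inside the predicted lung), `rate_all` (all-points
#'   denominator), `n_in_lung`, `n_points`.
#' @export
inclusion_rate <- function(pred, tree, k) {
  stopifnot(inherits(pred, "label_volume"))
  grid <- pred$grid
  pts <- labeled_centerline_points(tree, step = min(grid$spacing) / 2)
  pts <- pts[pts$label == k, , drop = FALSE]
  if (nrow(pts) == 0L) {
    warning("segment ", k, " absent from tree; inclusion rate missing")
    return(list(rate = NA_real_, rate_all = NA_real_, n_in_lung = 0L,
                n_points = 0L))
  }
  vox <- world_to_voxel(grid, as.matrix(pts[, c("x", "y", "z")]))
  ok <- in_grid(grid, vox)
  vox <- vox[ok, , drop = FALSE]
  lab <- pred$data[vox]
  inside <- lab != 0L
  rate <- if (any(inside)) mean(lab[inside] == k) else NA_real_
  list(rate = rate,
       rate_all = if (length(lab)) mean(lab == k) else NA_real_,
       n_in_lung = sum(inside), n_points = nrow(pts))
}

#' Evaluate a segment parcellation against a reference
#'
#' Computes Dice, HD95 (mm), ASSD (mm) and the bronchial inclusion rate for
#' each of the 18 segment codes, plus mean and sample (n-1) standard
#' deviation across segments defined in both masks. Metrics for segments
#' missing from either mask are reported missing (with a warning) and
#' excluded from the aggregates.
#'
#' @param pred predicted segment [label_volume].
#' @param ref reference segment [label_volume] on the same grid.
#' @param tree labeled [airway_tree] (for the inclusion rate); `NULL` skips
#'   that metric.
#' @param tax a [build_taxonomy()] object.
#' @return An object of class `metrics_report`: list with `per_segment` (18-
#'   row data frame) and `aggregate` (mean/sd per metric).
#' @export
evaluate <- function(pred, ref, tree = NULL, tax = build_taxonomy()) {
  stopifnot(inherits(pred, "label_volume"), inherits(ref, "label_volume"))
  if (!grids_equal(pred$grid, ref$grid)) stop("volumes are on different grids")
  codes <- tax$segments$code
  per <- data.frame(code = codes, lobe = tax$segments$lobe,
                    dice = NA_real_, hd95 = NA_real_, assd = NA_real_,
                    inclusion_rate = NA_real_, inclusion_rate_all = NA_real_)
  for (r in seq_along(codes)) {
    k <- codes[r]
    a <- pred$data == k
    b <- ref$data == k
    if (!any(a) && !any(b)) {
      warning("segment ", k, " empty in both masks; metrics missing")
      next
    }
    per$dice[r] <- 2 * sum(a & b) / (sum(a) + sum(b))
    if (any(a) && any(b)) {
      sd_ <- surface_distances(a, b, pred$grid$spacing)
      per$hd95[r] <- sd_$hd95
      per$assd[r] <- sd_$assd
    } else {
      warning("segment ", k, " empty in one mask; surface distances missing")
    }
    if (!is.null(tree)) {
      ir <- suppressWarnings(inclusion_rate(pred, tree, k))
      per$inclusion_rate[r] <- ir$rate
      per$inclusion_rate_all[r] <- ir$rate_all
    }
  }
  agg <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(mean = NA_real_, sd = NA_real_))
    c(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0)
  }
  aggregate <- list(dice = agg(per$dice), hd95 = agg(per$hd95),
                    assd = agg(per$assd),
                    inclusion_rate = agg(per$inclusion_rate))
  structure(list(per_segment = per, aggregate = aggregate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  a <- x$aggregate
  cat("<metrics_report> aggregates over",
      sum(!is.na(x$per_segment$dice)), "segments\n")
  cat(sprintf("  Dice           : %6.2f (SD = %.2f)  [x100]\n",
              100 * a$dice["mean"], 100 * a$dice["sd"]))
  cat(sprintf("  HD95 (mm)      : %6.2f (SD = %.2f)\n",
              a$hd95["mean"], a$hd95["sd"]))
  cat(sprintf("  ASSD (mm)      : %6.2f (SD = %.2f)\n",
              a$assd["mean"], a$assd["sd"]))
  if (!is.na(a$inclusion_rate["mean"]))
    cat(sprintf("  Inclusion rate : %6.2f (SD = %.2f)\n",
                a$inclusion_rate["mean"], a$inclusion_rate["sd"]))
  invisible(x)
}

#' Serialize a metrics report
#'
#' JSON carries per-segment rows (stored on the 0-1 scale for Dice and
#' inclusion rate) and the aggregates; the CSV is one flat row per segment.
#'
#' @param report a `metrics_report`.
#' @param path output file.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  obj <- list(schema = "lungparc-metrics-1",
              per_segment = report$per_segment,
              aggregate = lapply(report$aggregate, as.list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_metrics_json
#' @export
write_metrics_csv <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  utils::write.csv(report$per_segment, path, row.names = FALSE)
  invisible(path)
}
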