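make_label_pair <- function(dim = c(10, 10, 10)) {
  g <- image_grid(dim)
  a <- array(0L, dim)
  b <- array(0L, dim)
  list(g = g, a = a, b = b)
}

test_that("dice covers the closed-form cases", {
  p <- make_label_pair()
  p$a[3:4, 3:4, 3] <- 1L
  A <- label_volume(p$a, p$g)
  expect_equal(dice(A, A, 1L), 1.0)

  p$b[7:8, 7:8, 7] <- 1L
  B <- label_volume(p$b, p$g)
  expect_equal(dice(A, B, 1L), 0.0)

  # |A|=4, |B|=4, overlap 2 -> 0.5
  p$b[] <- 0L
  p$b[3:4, 3, 3] <- 1L
  p$b[5:6, 4, 3] <- 1L
  p$a[] <- 0L
  p$a[3:4, 3, 3] <- 1L
  p$a[7:8, 4, 3] <- 1L
  expect_equal(dice(label_volume(p$a, p$g), label_volume(p$b, p$g), 1L), 0.5)

  # both empty -> missing
  expect_true(is.na(dice(A, B, 7L)))
  # symmetric
  expect_equal(dice(A, B, 1L), dice(B, A, 1L))

  g2 <- image_grid(c(5, 5, 5))
  expect_error(dice(A, label_volume(array(0L, c(5, 5, 5)), g2), 1L),
               "different grids")
})

test_that("surface distances cover identity, the 3 mm pair, and the oracle", {
  d <- c(10, 10, 10)
  m <- array(FALSE, d); m[4:6, 4:6, 4:6] <- TRUE
  sd0 <- surface_distances(m, m)
  expect_equal(sd0$hd95, 0)
  expect_equal(sd0$assd, 0)

  a <- array(FALSE, d); a[4, 4, 4] <- TRUE
  b <- array(FALSE, d); b[7, 4, 4] <- TRUE
  sd3 <- surface_distances(a, b, spacing = c(1, 1, 1))
  expect_equal(sd3$hd95, 3.0)
  expect_equal(sd3$assd, 3.0)

  set.seed(77)
  for (rep in 1:3) {
    d <- c(15, 15, 15)
    a <- array(stats::runif(prod(d)) < 0.1, d)
    b <- array(stats::runif(prod(d)) < 0.1, d)
    if (!any(a)) a[2, 2, 2] <- TRUE
    if (!any(b)) b[3, 3, 3] <- TRUE
    got <- surface_distances(a, b, spacing = c(1, 2, 1))
    ora <- oracle_surface_distances(a, b, spacing = c(1, 2, 1))
    expect_equal(sort(got$pooled), sort(ora$pooled), tolerance = 1e-9)
    expect_equal(got$hd95, stats::quantile(ora$pooled, 0.95, type = 7,
                                           names = FALSE), tolerance = 1e-9)
    expect_equal(got$assd, mean(ora$pooled), tolerance = 1e-9)
    expect_lte(got$hd95, max(got$pooled))
    expect_lte(got$assd, max(got$pooled))
  }
  expect_error(surface_distances(array(FALSE, d), b), "non-empty")
})

test_that("inclusion rate counts labeled centerline points inside the prediction", {
  g <- image_grid(c(24, 12, 12))
  # 12 labeled nodes fanned off an unlabeled root: no labeled-labeled edges,
  # so the point set is exactly the 12 node voxels
  tr <- airway_tree(data.frame(id = 1:13, x = c(2, 5:16), y = 6, z = 6,
                               parent = c(-1, rep(1L, 12)),
                               label = c(NA, rep(4L, 12))))
  pred <- array(0L, g$dim)
  pred[3:20, 3:10, 3:10] <- 5L      # surrounding lobe labeled as B5
  # the 12 labeled point voxels (x = 5..16 -> index 6..17): 9 correct, 3 wrong
  pred[cbind(6:17, 7, 7)] <- c(rep(4L, 9), rep(5L, 3))
  P <- label_volume(pred, g)
  ir <- inclusion_rate(P, tr, 4L)
  expect_equal(ir$rate, 0.75)
  expect_equal(ir$n_in_lung, 12L)

  # fully relabeled -> 0
  pred[cbind(6:17, 7, 7)] <- 5L
  expect_equal(inclusion_rate(label_volume(pred, g), tr, 4L)$rate, 0.0)

  # absent segment -> missing with warning
  expect_warning(miss <- inclusion_rate(P, tr, 9L), "absent")
  expect_true(is.na(miss$rate))
})

test_that("inclusion rate is 1 for a self-consistent parcellation", {
  mp <- make_mini_phantom(seed = 555)
  seg <- suppressWarnings(nearest_bronchus_parcellation(mp$lobes, mp$tree))
  # restrict to segments whose points actually fall in their own lobe mask
  pts <- lungparc:::labeled_centerline_points(mp$tree, 0.5)
  vox <- world_to_voxel(mp$grid, as.matrix(pts[, c("x", "y", "z")]))
  inside <- mp$lobes$data[vox] != 0L
  for (k in unique(pts$label[inside])) {
    sel <- pts$label == k
    if (all(mp$lobes$data[vox[sel, , drop = FALSE]] ==
            lobe_codes(build_taxonomy())[lobe_of(build_taxonomy(), k)])) {
      ir <- inclusion_rate(seg, mp$tree, k)
      expect_equal(ir$rate, 1.0)
    }
  }
})

test_that("evaluate aggregates per-segment metrics with sample SD", {
  ph <- get_phantom(42)
  rep_ <- suppressWarnings(evaluate(ph$segments_gt, ph$segments_gt, ph$tree))
  expect_s3_class(rep_, "metrics_report")
  expect_equal(nrow(rep_$per_segment), 18L)
  expect_equal(rep_$aggregate$dice[["mean"]], 1.0)
  expect_equal(rep_$aggregate$dice[["sd"]], 0.0)
  expect_equal(rep_$aggregate$hd95[["mean"]], 0.0)
  expect_equal(rep_$aggregate$assd[["mean"]], 0.0)
  expect_equal(rep_$aggregate$inclusion_rate[["mean"]], 1.0)

  # closed-form aggregate: mean(1, .5) = .75, sd = 0.3536
  x <- c(1, 0.5)
  expect_equal(mean(x), 0.75)
  expect_equal(stats::sd(x), 0.3535534, tolerance = 1e-6)

  # serialization: JSON + CSV with one row per segment
  fj <- tempfile(fileext = ".json")
  fc <- tempfile(fileext = ".csv")
  write_metrics_json(rep_, fj)
  write_metrics_csv(rep_, fc)
  js <- jsonlite::fromJSON(fj)
  expect_equal(js$schema, "lungparc-metrics-1")
  expect_equal(nrow(js$per_segment), 18L)
  expect_equal(js$aggregate$dice$mean, 1.0)
  csv <- utils::read.csv(fc)
  expect_equal(nrow(csv), 18L)
})

test_that("metrics ignore the labels of other segments", {
  mp <- make_mini_phantom(seed = 888)
  seg <- suppressWarnings(nearest_bronchus_parcellation(mp$lobes, mp$tree))
  k <- setdiff(unique(as.vector(seg$data)), 0L)[1]
  other <- setdiff(unique(as.vector(seg$data)), c(0L, k))[1]
  relab <- seg
  relab$data[relab$data == other] <- 17L
  a <- seg$data == k
  expect_equal(dice(seg, relab, k), 1.0)
  s1 <- surface_distances(a, relab$data == k, seg$grid$spacing)
  expect_equal(s1$hd95, 0)
})
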