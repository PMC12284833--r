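test_that("geodesic time behaves like distance/speed in the constant-speed limit", {
  g <- image_grid(c(21, 21, 21))
  prob <- scalar_volume(array(1, g$dim), g)
  T1 <- geodesic_time(prob, c(11, 11, 11))
  expect_equal(T1$data[11, 11, 11], 0)
  # 5 mm along an axis at speed 1: T ~ 5 within fast-marching tolerance
  expect_equal(T1$data[16, 11, 11], 5, tolerance = 0.05 * 5)
  expect_true(all(is.finite(T1$data)))

  # halving the speed doubles every arrival time
  T2 <- geodesic_time(scalar_volume(array(0.5, g$dim), g), c(11, 11, 11))
  expect_equal(T2$data, 2 * T1$data, tolerance = 1e-9)

  expect_error(geodesic_time(prob, c(0, 1, 1)), "seed")
  expect_error(geodesic_time(prob, c(22, 1, 1)), "seed")
})

test_that("a straight tube traces to a single accurate branch", {
  g <- image_grid(c(20, 20, 40))
  tube <- airway_tree(data.frame(id = 1:2, x = 9, y = 9, z = c(4, 34),
                                 parent = c(-1, 1)))
  prob <- centerline_probability(tube, g)
  tr <- trace(prob)
  expect_length(validate_tree(tr), 0L)
  expect_length(branch_decomposition(tr), 1L)
  # nodes within one voxel (max spacing) of the true axis
  expect_lte(max(sqrt((tr$x - 9)^2 + (tr$y - 9)^2)), max(g$spacing))
  expect_gte(tree_recovery_fraction(tube, tr, tol_mm = 1.5), 0.95)
})

test_that("a Y-shaped tube traces to one bifurcation with generations 0/1/1", {
  g <- image_grid(c(31, 31, 40))
  ytree <- airway_tree(data.frame(id = 1:4, x = c(15, 15, 7, 23), y = 15,
                                  z = c(4, 18, 32, 32),
                                  parent = c(-1, 1, 2, 2)))
  prob <- centerline_probability(ytree, g)
  tr <- trace(prob, seed = c(16, 16, 5))
  br <- branch_decomposition(tr)
  expect_length(br, 3L)
  expect_equal(sort(vapply(br, `[[`, integer(1), "generation")), c(0L, 1L, 1L))
  expect_equal(count_branch_points(tr), 1L)
  expect_length(validate_tree(tr), 0L)
})

test_that("marching bridges a 2 mm probability gap into a single rooted tree", {
  g <- image_grid(c(20, 20, 40))
  tube <- airway_tree(data.frame(id = 1:2, x = 9, y = 9, z = c(4, 34),
                                 parent = c(-1, 1)))
  prob <- centerline_probability(tube, g)
  gapped <- inject_gap(prob, tube, 1L, gap_mm = 2)
  expect_gt(sum(gapped$data == 0 & prob$data > 0.05), 0)
  tr <- trace(gapped, seed = c(10, 10, 5))
  expect_length(validate_tree(tr), 0L)
  expect_equal(sum(tr$parent == -1L), 1L)
  # the distal side of the gap is still reached
  expect_gt(max(tr$z), 30)
  expect_gte(tree_recovery_fraction(tube, tr, tol_mm = 1.5), 0.90)
})

test_that("tracing is deterministic and validates parameters", {
  g <- image_grid(c(20, 20, 30))
  tube <- airway_tree(data.frame(id = 1:2, x = 9, y = 9, z = c(4, 24),
                                 parent = c(-1, 1)))
  prob <- centerline_probability(tube, g)
  expect_identical(trace(prob), trace(prob))

  expect_error(tracer_params(prob_threshold = 0), "prob_threshold")
  expect_error(tracer_params(prob_threshold = 1), "prob_threshold")
  expect_error(tracer_params(speed_floor = 0), "speed_floor")
  expect_error(tracer_params(coverage_fraction = 1.2), "coverage_fraction")
  expect_error(tracer_params(min_branch_nodes = 0), "min_branch_nodes")
  # coverage_fraction = 1 is allowed (closed upper bound)
  expect_s3_class(tracer_params(coverage_fraction = 1), "tracer_params")

  empty <- scalar_volume(array(0.001, c(5, 5, 5)), image_grid(c(5, 5, 5)))
  expect_error(trace(empty), "no foreground")
})

test_that("traced trees are valid for assorted seeds and params", {
  g <- image_grid(c(25, 25, 30))
  ytree <- airway_tree(data.frame(id = 1:4, x = c(12, 12, 6, 18), y = 12,
                                  z = c(3, 12, 24, 24),
                                  parent = c(-1, 1, 2, 2)))
  prob <- centerline_probability(ytree, g)
  for (sd in list(NULL, c(13, 13, 4), c(12, 12, 10))) {
    tr <- trace(prob, tracer_params(coverage_fraction = 0.9), seed = sd)
    expect_length(validate_tree(tr), 0L)
  }
})
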