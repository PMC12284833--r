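test_that("a lobe served by a single segment is labeled wholesale", {
  g <- image_grid(c(20, 20, 20))
  lob <- array(0L, g$dim)
  lob[4:16, 4:16, 4:16] <- 1L  # RUL
  lobes <- label_volume(lob, g)
  tr <- airway_tree(data.frame(id = 1:3, x = c(10, 10, 10), y = 10,
                               z = c(12, 10, 8), parent = c(-1, 1, 2),
                               label = c(NA, 1L, 1L)))
  expect_warning(seg <- nearest_bronchus_parcellation(lobes, tr),
                 "no labeled bronchus")  # RUL's B2/B3 have no nodes
  expect_true(all(seg$data[lob == 1L] == 1L))
  expect_true(all(seg$data[lob == 0L] == 0L))
  expect_equal(dice(seg, lobes, 1L), 1.0)  # segment mask == lobe mask
})

test_that("production parcellation equals the exhaustive oracle on mini phantoms", {
  for (s in 1:6) {
    mp <- make_mini_phantom(seed = 100 + s)
    seg <- suppressWarnings(nearest_bronchus_parcellation(mp$lobes, mp$tree))
    ora <- oracle_parcellation(mp$lobes, mp$tree)
    expect_identical(seg$data, ora$data)
    # partition: labeled voxels are exactly the lobe voxels
    expect_identical(seg$data != 0L, mp$lobes$data != 0L)
  }
})

test_that("segment labels never cross lobe boundaries", {
  tax <- build_taxonomy()
  mp <- make_mini_phantom(seed = 321)
  seg <- suppressWarnings(nearest_bronchus_parcellation(mp$lobes, mp$tree, tax))
  lcode <- lobe_codes(tax)
  for (lb in names(lcode)) {
    lin <- which(mp$lobes$data == lcode[[lb]])
    if (!length(lin)) next
    expect_true(all(seg$data[lin] %in% segments_for_lobe(tax, lb)))
  }
})

test_that("parcellation errors on unlabeled trees, bare lobes, grid mismatch", {
  g <- image_grid(c(10, 10, 10))
  lob <- array(0L, g$dim); lob[3:7, 3:7, 3:7] <- 1L
  lobes <- label_volume(lob, g)
  bare <- airway_tree(data.frame(id = 1, x = 5, y = 5, z = 5, parent = -1))
  expect_error(nearest_bronchus_parcellation(lobes, bare), "no segment labels")
  # lobe populated but its bronchi belong elsewhere
  wrong <- airway_tree(data.frame(id = 1:2, x = 5, y = 5, z = c(5, 6),
                                  parent = c(-1, 1), label = c(NA, 11L)))
  expect_error(suppressWarnings(nearest_bronchus_parcellation(lobes, wrong)),
               "no candidate bronchi")
})

test_that("lobe regularization fixes strays, fills holes, zeroes non-lung", {
  tax <- build_taxonomy()
  g <- image_grid(c(16, 16, 16))
  lob <- array(0L, g$dim)
  lob[3:13, 3:13, 3:8] <- 1L    # RUL
  lob[3:13, 3:13, 9:14] <- 3L   # RLL
  lobes <- label_volume(lob, g)
  seg <- array(0L, g$dim)
  seg[3:13, 3:13, 3:8] <- 1L    # right B1
  seg[3:13, 3:13, 9:14] <- 6L   # right B6
  clean <- label_volume(seg, g)
  # already consistent: fixed point
  expect_identical(regularize_by_lobes(clean, lobes, tax)$data, clean$data)

  dirty <- seg
  dirty[8, 8, 5] <- 6L           # RLL code stranded inside RUL
  dirty[4, 4, 4] <- 0L           # hole inside RUL
  dirty[1, 1, 1] <- 2L           # segment voxel outside the lungs
  reg <- regularize_by_lobes(label_volume(dirty, g), lobes, tax)
  expect_equal(reg$data[8, 8, 5], 1L)
  expect_equal(reg$data[4, 4, 4], 1L)
  expect_equal(reg$data[1, 1, 1], 0L)
  expect_identical(reg$data != 0L, lob != 0L)
  # idempotent
  expect_identical(regularize_by_lobes(reg, lobes, tax)$data, reg$data)
})

test_that("a lobe with no valid segment voxels falls back to its lowest code", {
  tax <- build_taxonomy()
  g <- image_grid(c(10, 10, 10))
  lob <- array(0L, g$dim); lob[3:7, 3:7, 3:7] <- 2L  # RML only
  seg <- array(0L, g$dim)
  expect_warning(reg <- regularize_by_lobes(label_volume(seg, g),
                                            label_volume(lob, g), tax),
                 "no valid segment voxels")
  expect_true(all(reg$data[lob == 2L] == 4L))  # right B4
})

test_that("crop_resample is the identity on the trivial case", {
  g <- image_grid(c(12, 14, 16), c(1, 1, 1))
  vol <- scalar_volume(array(stats::runif(prod(g$dim)), g$dim), g)
  lm <- landmarks(c(3, 3, 3), c(8, 8, 8))
  out <- crop_resample(vol, lm, out_spacing = 1, margin_mm = c(100, 100, 100))
  expect_equal(out$grid$dim, g$dim)
  expect_equal(out$data, vol$data, tolerance = 1e-12)

  lab <- label_volume(array(sample(0:3, prod(g$dim), TRUE), g$dim), g)
  outl <- crop_resample(lab, lm, out_spacing = 1, margin_mm = c(100, 100, 100))
  expect_identical(outl$data, lab$data)
})

test_that("label resampling never invents labels and spacing lands at 2 mm", {
  g <- image_grid(c(24, 24, 24), c(1, 1, 1))
  lab <- label_volume(array(sample(c(0L, 1L, 6L, 11L), prod(g$dim), TRUE),
                            g$dim), g)
  lm <- landmarks(c(6, 6, 6), c(18, 18, 18))
  out <- crop_resample(lab, lm, out_spacing = 2, margin_mm = c(4, 4, 4))
  expect_equal(out$grid$spacing, c(2, 2, 2))
  expect_true(all(unique(as.vector(out$data)) %in% unique(as.vector(lab$data))))
  expect_s3_class(out, "label_volume")

  expect_error(crop_resample(lab, landmarks(c(-50, 6, 6), c(18, 18, 18))),
               "outside the volume")
})

test_that("NIfTI round trip preserves grid geometry and voxel payload", {
  g <- image_grid(c(7, 8, 9), c(0.5, 1, 2), c(-10, 5, 0))
  vol <- scalar_volume(array(stats::runif(prod(g$dim)), g$dim), g)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f, "scalar")
  expect_equal(back$grid$dim, g$dim)
  expect_equal(back$grid$spacing, g$spacing, tolerance = 1e-5)
  expect_equal(back$grid$origin, g$origin, tolerance = 1e-4)
  expect_equal(back$data, vol$data, tolerance = 1e-6)  # float32 storage

  lab <- label_volume(array(sample(0:18, prod(g$dim), TRUE), g$dim), g)
  fl <- tempfile(fileext = ".nii.gz")
  write_volume(lab, fl)
  backl <- read_volume(fl, "label")
  expect_identical(backl$data, lab$data)
})
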