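test_that("NIfTI round-trip preserves voxels, geometry and presence flags", {
  co <- small_cohort()
  case <- co$cases[[1]]
  dir <- withr::local_tempdir()
  entry <- write_case(case, dir)
  back <- read_case(entry, dir, structures = case$pre$structures$names)
  expect_equal(back$pre$image$voxels, case$pre$image$voxels, tolerance = 1e-6)
  expect_equal(back$pre$image$spacing, case$pre$image$spacing)
  expect_equal(back$mid$image$origin, case$mid$image$origin, tolerance = 1e-4)
  for (tp in c("pre", "mid")) {
    expect_equal(back[[tp]]$structures$present, case[[tp]]$structures$present)
    for (s in case[[tp]]$structures$names)
      expect_identical(back[[tp]]$structures$masks[[s]],
                       case[[tp]]$structures$masks[[s]])
  }
})

test_that("label files are binarized at 0.5 on load", {
  dir <- withr::local_tempdir()
  arr <- array(0, c(6, 6, 6)); arr[2:4, 2:4, 2:4] <- 2  # values {0, 2}
  f <- file.path(dir, "lab.nii.gz")
  adaptseg:::write_nifti_vol(arr, c(1, 1, 1), c(0, 0, 0), f)
  v <- adaptseg:::read_nifti_vol(f)
  ss <- structure_set(list(a = v$voxels), v$spacing, v$origin)
  expect_setequal(unique(as.vector(ss$masks$a)), c(TRUE, FALSE))
  expect_equal(sum(ss$masks$a), 27)
})

test_that("mask/image geometry mismatch within a timepoint is an error", {
  co <- small_cohort()
  case <- co$cases[[1]]
  dir <- withr::local_tempdir()
  entry <- write_case(case, dir)
  # overwrite one label with a wrong-sized volume
  adaptseg:::write_nifti_vol(array(1, c(4, 4, 4)), c(2, 2, 2), c(0, 0, 0),
                             file.path(dir, entry$pre$labels[["bone"]]))
  expect_error(read_case(entry, dir), "geometry")
  expect_error(read_case(list(patient_id = "x",
                              pre = list(image = "missing.nii.gz",
                                         labels = list()),
                              mid = entry$mid), dir),
               "not found")
})

test_that("resampling preserves identity, extent and constants", {
  v <- image_volume(array(rnorm(10 * 12 * 8), c(10, 12, 8)), c(2, 2, 2),
                    c(5, -3, 0))
  expect_equal(resample(v, v$spacing)$voxels, v$voxels)
  r <- resample(v, c(1, 1, 1))
  expect_equal(dim(r$voxels), c(20L, 24L, 16L))
  # physical extent preserved within one voxel
  expect_lt(max(abs(dim(r$voxels) * r$spacing - dim(v$voxels) * v$spacing)), 1)
  cst <- image_volume(array(7, c(8, 8, 8)), c(2, 2, 2))
  expect_equal(range(resample(cst, c(1.3, 0.7, 2.9))$voxels), c(7, 7),
               tolerance = 1e-12)
  expect_error(resample(v, c(0, 1, 1)), "positive")
})

test_that("resampled grids agree with an independent coordinate mapping", {
  # linear ramp along x: value = world x coordinate; linear interpolation
  # must reproduce the ramp exactly at any resampled position
  d <- c(12, 6, 6)
  wx <- array(rep((0:11) * 2 + 1, times = 36), d)
  v <- image_volume(wx, c(2, 2, 2), c(1, 0, 0))
  r <- resample(v, c(0.9, 2, 2))
  interior <- 3:(dim(r$voxels)[1] - 3)
  expected <- r$origin[1] + (interior - 1) * r$spacing[1]
  expect_equal(r$voxels[interior, 3, 3], expected, tolerance = 1e-10)
})

test_that("cropping honours extent, padding and overlap contracts", {
  v <- image_volume(array(rnorm(8^3, mean = 100), c(8, 8, 8)), c(1, 1, 2))
  ctr <- adaptseg:::grid_center(v)
  same <- crop_to_region(v, ctr, dim(v$voxels) * v$spacing)
  expect_equal(same$voxels, v$voxels)
  # half-in/half-out: out-of-field voxels equal the background fill
  off <- crop_to_region(v, ctr + c(4, 0, 0), dim(v$voxels) * v$spacing)
  expect_true(all(off$voxels[5:8, , ] == min(v$voxels)))
  expect_equal(off$voxels[1:4, , ], v$voxels[5:8, , ])
  expect_error(crop_to_region(v, ctr + c(100, 0, 0), c(4, 4, 4)), "overlap")
  # grid shape = extent / spacing
  big <- image_volume(array(0, c(40, 40, 30)), c(10, 10, 10))
  crop <- crop_to_region(big, adaptseg:::grid_center(big), c(330, 400, 500))
  expect_equal(dim(crop$voxels), c(33L, 40L, 50L))
})

test_that("geometry operations commute with intensity shifts", {
  v <- image_volume(array(rnorm(10^3), c(10, 10, 10)), c(2, 2, 2))
  vs <- image_volume(v$voxels + 11, v$spacing, v$origin)
  r1 <- resample(v, c(1.5, 1.5, 1.5))$voxels + 11
  r2 <- resample(vs, c(1.5, 1.5, 1.5))$voxels
  expect_equal(r1, r2, tolerance = 1e-10)
  ctr <- adaptseg:::grid_center(v)
  c1 <- crop_to_region(v, ctr + 2, c(12, 12, 12))$voxels + 11
  c2 <- crop_to_region(vs, ctr + 2, c(12, 12, 12))$voxels
  expect_equal(c1, c2, tolerance = 1e-10)
})

test_that("crop then pad-back reconstructs values inside the crop exactly", {
  v <- image_volume(array(rnorm(10^3), c(10, 10, 10)), c(2, 2, 2))
  ctr <- adaptseg:::grid_center(v)
  cropped <- crop_to_region(v, ctr, c(12, 12, 12))
  back <- crop_to_region(cropped, ctr, c(20, 20, 20))
  inner <- 3:8
  expect_equal(back$voxels[inner, inner, inner], v$voxels[inner, inner, inner])
})

test_that("mask resample round-trip preserves component count on convex shapes", {
  m <- array(FALSE, c(12, 12, 12)); m[4:9, 4:9, 4:9] <- TRUE
  ss <- structure_set(list(cube = m), c(2, 2, 2))
  down <- resample(ss, c(3, 3, 3))
  up <- resample(down, c(2, 2, 2))
  lab <- adaptseg:::label_components_cpp(as.logical(up$masks$cube), c(12L, 12L, 12L), 26L)
  expect_equal(attr(lab, "n"), 1L)
  expect_true(all(vapply(up$masks, is.logical, TRUE)))
})

test_that("structure sets enforce binary masks, shared grids and absent zeroing", {
  m <- array(runif(4^3), c(4, 4, 4))
  ss <- structure_set(list(a = m, b = m > 0.5), c(1, 1, 1),
                      present = c(a = TRUE, b = FALSE))
  expect_true(is.logical(ss$masks$a))
  expect_true(all(!ss$masks$b))  # absent => all-zero mask
  expect_error(structure_set(list(a = m, b = array(0, c(3, 3, 3))), c(1, 1, 1)),
               "grid shape")
})

test_that("cohort manifest round-trips through write_cohort/read_cohort", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co$cases[1:2], dir, extra = list(phantom = co$manifest))
  back <- read_cohort(dir)
  expect_named(back, names(co$cases)[1:2])
  expect_equal(back[[1]]$pre$image$voxels, co$cases[[1]]$pre$image$voxels,
               tolerance = 1e-6)
  mf <- attr(back, "manifest")
  expect_equal(unlist(mf$structures), co$cases[[1]]$pre$structures$names)
  expect_true(!is.null(mf$phantom$patients[[1]]$transform_pre_to_mid))
})
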