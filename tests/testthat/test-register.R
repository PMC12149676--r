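test_that("mutual information matches hand-computed entropy values", {
  # two-level image, p = (0.5, 0.5): MI(a, a) = H = ln 2
  a <- image_volume(array(rep(c(0, 1), each = 500), c(10, 10, 10)), c(1, 1, 1))
  expect_equal(mutual_information(a, a), log(2), tolerance = 1e-12)
  # four equiprobable levels: H = ln 4
  b <- image_volume(array(rep(0:3, each = 250), c(10, 10, 10)), c(1, 1, 1))
  expect_equal(mutual_information(b, b), log(4), tolerance = 1e-12)
})

test_that("mutual information is symmetric and vanishes under independence", {
  set.seed(8)
  a <- image_volume(array(rnorm(16^3), c(16, 16, 16)), c(1, 1, 1))
  b <- image_volume(array(sample(a$voxels), c(16, 16, 16)), c(1, 1, 1))
  expect_equal(mutual_information(a, b), mutual_information(b, a))
  expect_lt(mutual_information(a, b, bins = 8), 0.05)
  expect_gt(mutual_information(a, a), 1)
  cst <- image_volume(array(1, c(8, 8, 8)), c(1, 1, 1))
  expect_warning(mi0 <- mutual_information(cst, cst), "constant")
  expect_equal(mi0, 0)
})

test_that("mutual information is invariant to joint monotone rebinning", {
  set.seed(9)
  a <- image_volume(array(rnorm(12^3), c(12, 12, 12)), c(1, 1, 1))
  b <- image_volume(array(rnorm(12^3) + 0.5 * a$voxels, c(12, 12, 12)), c(1, 1, 1))
  m1 <- mutual_information(a, b, bins = 16)
  # strictly increasing affine relabeling of both images
  a2 <- image_volume(3 * a$voxels + 10, a$spacing)
  b2 <- image_volume(0.5 * b$voxels - 4, b$spacing)
  expect_equal(mutual_information(a2, b2, bins = 16), m1, tolerance = 1e-10)
})

test_that("rigid transforms compose with their inverse to identity", {
  set.seed(3)
  t <- rigid_transform(runif(3, -10, 10), runif(3, -20, 20), c(5, 5, 5))
  inv <- rigid_invert(t)
  pts <- matrix(rnorm(30, sd = 40), 3)
  back <- rigid_apply(inv, rigid_apply(t, pts))
  expect_lt(max(abs(back - pts)), 1e-6)
  R <- adaptseg:::euler_to_matrix(t$rotation)
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
})

test_that("registering an image to itself recovers the identity", {
  co <- small_cohort()
  fixed <- co$cases[[1]]$pre$image
  t <- register_rigid(fixed, fixed)
  expect_lt(max(abs(t$translation)), 0.5)
  expect_lt(max(abs(t$rotation)), 0.5)
})

test_that("known translations and rotations are recovered", {
  co <- small_cohort()
  fixed <- co$cases[[1]]$pre$image
  ctr <- adaptseg:::grid_center(fixed)
  gt <- rigid_transform(c(0, 0, 0), c(5, 0, 0), ctr)
  moving <- warp(fixed, rigid_invert(gt), fixed)
  t <- register_rigid(fixed, moving)
  expect_lt(max(abs(t$translation - gt$translation)), 1)
  gt2 <- rigid_transform(c(0, 0, 3), c(0, 0, 0), ctr)
  moving2 <- warp(fixed, rigid_invert(gt2), fixed)
  t2 <- register_rigid(fixed, moving2)
  expect_lt(max(abs(t2$rotation - gt2$rotation)), 1)
})

test_that("warping respects interpolation contracts", {
  co <- small_cohort()
  img <- co$cases[[1]]$pre$image
  ss <- co$cases[[1]]$pre$structures
  idt <- rigid_transform()
  expect_equal(warp(img, idt)$voxels, img$voxels)
  expect_identical(warp(ss, idt)$masks, ss$masks)
  # integer-voxel translation: shifted mask, count preserved in interior
  t1 <- rigid_transform(translation = c(ss$spacing[1], 0, 0))
  w <- warp(ss, t1)
  expect_true(is.logical(w$masks$bone))
  expect_equal(sum(w$masks$bone), sum(ss$masks$bone))
  expect_identical(unname(w$masks$bone[1:40, , ]), unname(ss$masks$bone[2:41, , ]))
  # warp then inverse-warp: bounded deviation on the smooth interior
  t2 <- rigid_transform(c(2, -1, 1), c(3, -2, 1), adaptseg:::grid_center(img))
  there <- warp(img, t2)
  back <- warp(there, rigid_invert(t2))
  core <- 13:36
  expect_lt(mean(abs(back$voxels[core, core, core] -
                     img$voxels[core, core, core])), 30)
  # no foreground is created outside the warped support
  empty <- structure_set(list(a = array(FALSE, dim(img$voxels))),
                         img$spacing, img$origin)
  expect_equal(sum(warp(empty, t2)$masks$a), 0)
})

test_that("transform JSON serialization round-trips", {
  t <- rigid_transform(c(1.5, -2, 0.25), c(3, 4, -5), c(10, 20, 30))
  f <- withr::local_tempfile(fileext = ".json")
  write_transform(t, f)
  back <- read_transform(f)
  expect_equal(back$rotation, t$rotation)
  expect_equal(back$translation, t$translation)
  expect_equal(back$center, t$center)
})

test_that("RIR propagation is exact for identical timepoints and accurate for rigid ones", {
  cfg <- phantom_config(n_patients = 1, translation_mm = 0, rotation_deg = 0,
                        deform_amplitude_mm = 0, shrinkage_range = c(1, 1),
                        noise_sd = 0, seed = 12)
  case <- generate_cohort(cfg)$cases[[1]]
  pred <- rir_segment(case)
  for (s in pred$names)
    expect_equal(dsc(pred$masks[[s]], case$mid$structures$masks[[s]]),
                 1, ignore_attr = TRUE)
})

test_that("local deformation degrades RIR on deformable structures only", {
  cfg <- phantom_config(n_patients = 2, deform_amplitude_mm = 6,
                        shrinkage_range = c(1, 1), noise_sd = 10, seed = 13)
  co <- generate_cohort(cfg)
  ds <- sapply(co$cases, function(case) {
    pred <- rir_segment(case)
    c(rigid = dsc(pred$masks$bone, case$mid$structures$masks$bone),
      deformable = dsc(pred$masks$plexus, case$mid$structures$masks$plexus))
  })
  expect_gt(mean(ds["rigid", ]), mean(ds["deformable", ]) + 0.05)
})
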