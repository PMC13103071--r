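test_that("clean generation is deterministic and matches ellipsoid volume", {
  rec <- small_recipe()
  m1 <- generate_clean(rec, seed = 5)
  m2 <- generate_clean(rec, seed = 5)
  expect_identical(m1$voxels, m2$voxels)
  expect_false(identical(m1$voxels, generate_clean(rec, seed = 6)$voxels))

  exact <- small_recipe(axis_jitter = 0, center_jitter = 0,
                        deform_amplitude = 0)
  m <- generate_clean(exact, seed = 1)
  analytic <- 4 / 3 * pi * prod(exact$semi_axes)
  vol <- sum(m$voxels) * prod(exact$spacing)
  expect_lt(abs(vol - analytic) / analytic, 0.03)

  # single connected component, no border contact
  expect_equal(maskqc:::n_components(m1$voxels), 1L)
  f <- extract_features(m1)
  expect_equal(f[["border_voxel_count"]], 0)

  # axes that cannot fit the grid are rejected
  expect_error(generate_clean(mask_recipe(shape = c(32, 32, 32),
                                          spacing = c(1, 1, 1)),
                              seed = 1),
               class = "config_error")
})

test_that("corruptions change voxels, stay non-empty, and report Dice", {
  m <- generate_clean(small_recipe(), seed = 9)
  for (kind in c("erode", "dilate", "punch_holes", "add_blob",
                 "truncate_axial", "translate")) {
    mag <- switch(kind, erode = 1, dilate = 1, punch_holes = 6,
                  add_blob = 8, truncate_axial = 0.2, translate = 6)
    res <- corrupt_mask(m, corruption_spec(kind, mag, seed = 3))
    expect_gt(sum(abs(res$mask$voxels - m$voxels)), 0)
    expect_gt(sum(res$mask$voxels), 0)
    expect_equal(res$dice, dice(m, res$mask))
    expect_lt(res$dice, 1)
  }
  # zero translation is the identity
  res0 <- corrupt_mask(m, corruption_spec("translate", 0, seed = 3))
  expect_identical(res0$mask$voxels, m$voxels)
  expect_equal(res0$dice, 1)
  # corruption that would empty the mask raises
  expect_error(corrupt_mask(m, corruption_spec("erode", 20, seed = 1)),
               class = "maskqc_error")
})

test_that("erosion severity is monotone in Dice", {
  m <- generate_clean(small_recipe(), seed = 12)
  d <- vapply(1:3, function(s) {
    corrupt_mask(m, corruption_spec("erode", s, seed = 1))$dice
  }, numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("calibration lands corruptions in the sanity bands", {
  m <- generate_clean(small_recipe(), seed = 21)
  er <- calibrate_corruption(m, "erode", seed = 2)
  expect_lt(er$dice, 0.95)
  tr <- calibrate_corruption(m, "translate", seed = 2)
  expect_lt(tr$dice, 0.95)
  expect_gte(tr$dice, 0.80)
  bl <- calibrate_corruption(m, "add_blob", seed = 2)
  expect_gt(hd95(m, bl$mask), 15)
})

test_that("NIfTI round trip preserves voxels and spacing exactly", {
  m <- generate_clean(mask_recipe(shape = c(48, 48, 64), spacing = c(2, 2, 1.25),
                                  semi_axes = c(30, 24, 22)),
                      seed = 4)
  path <- tempfile(fileext = ".nii.gz")
  write_mask(m, path)
  m2 <- read_mask(path)
  expect_identical(m2$voxels, m$voxels)
  expect_equal(m2$spacing, m$spacing, tolerance = 1e-6)
})

test_that("cohort generation: manifest consistency and determinism", {
  dir1 <- file.path(tempdir(), "cohort-a")
  dir2 <- file.path(tempdir(), "cohort-b")
  man1 <- generate_cohort(dir1, n_clean = 4, n_corrupt = 4,
                          recipes = small_site_recipes(), seed = 31)
  man2 <- generate_cohort(dir2, n_clean = 4, n_corrupt = 4,
                          recipes = small_site_recipes(), seed = 31)
  expect_identical(man1[, names(man1) != "file"],
                   man2[, names(man2) != "file"])
  expect_equal(nrow(man1), 8L)
  expect_equal(sum(man1$status == "corrupt"), 4L)
  expect_true(all(man1$sanity_positive[man1$status == "corrupt"]))
  expect_false(any(man1$sanity_positive[man1$status == "clean"]))
  # manifest Dice/HD95 match recomputation from the written files
  for (j in which(man1$status == "corrupt")) {
    cand <- read_mask(file.path(dir1, man1$file[j]))
    src_row <- match(man1$source_id[j], man1$mask_id)
    gt <- read_mask(file.path(dir1, man1$file[src_row]))
    expect_equal(dice(gt, cand), man1$dice[j], tolerance = 1e-12)
    expect_equal(hd95(gt, cand), man1$hd95[j], tolerance = 1e-12)
  }
  # clean-only cohorts supported for baselines
  man0 <- generate_cohort(file.path(tempdir(), "cohort-c"), n_clean = 2,
                          n_corrupt = 0, recipes = small_site_recipes(),
                          seed = 1)
  expect_equal(nrow(man0), 2L)
})
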