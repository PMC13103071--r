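test_that("central moments: symmetry, degenerate cases, axis alignment", {
  cube <- cube_mask(10)
  mom <- compute_central_moments(cube)
  expect_equal(mom$matrix, t(mom$matrix), tolerance = 1e-12)
  # permutation-symmetric shape: all three eigenvalues coincide
  expect_lt(diff(range(mom$eigenvalues)), 1e-9 * mom$eigenvalues[1])

  single <- array(0L, c(5, 5, 5))
  single[3, 3, 3] <- 1L
  mom1 <- compute_central_moments(brain_mask(single))
  expect_equal(mom1$matrix, matrix(0, 3, 3))
  expect_equal(mom1$eigenvalues, c(0, 0, 0))

  box <- box_mask(c(20L, 10L, 10L))
  momb <- compute_central_moments(box)
  # extreme eigenvalue's eigenvector aligned with the long (x) axis
  expect_gt(abs(momb$eigenvectors[1, 1]), 0.999)

  expect_error(compute_central_moments(brain_mask(array(0L, c(4, 4, 4)))),
               class = "empty_mask_error")
})

test_that("central moments match the naive triple-sum oracle", {
  for (seed in c(11, 12, 13)) {
    m <- random_blob_mask(seed)
    mom <- compute_central_moments(m)
    ref <- oracle_moments(m)
    expect_equal(mom$matrix, ref, tolerance = 1e-9)
    # eigen-trace identity
    expect_equal(sum(diag(mom$matrix)), sum(mom$eigenvalues),
                 tolerance = 1e-9)
  }
})

test_that("feature extraction: counting, spacing, and sphere radius", {
  cube <- cube_mask(10)
  f <- extract_features(cube)
  expect_length(f, 23L)
  expect_true(all(is.finite(f)))
  expect_identical(attr(f, "mask_id"), "cube")
  expect_equal(f[["voxel_count"]], 1000)
  expect_equal(f[["physical_size"]], 1000)
  expect_equal(f[["surface_area"]], 600)
  expect_equal(f[["bbox_extent_1"]], 10)

  f2 <- extract_features(cube_mask(10, spacing = c(2, 1, 1)))
  expect_equal(f2[["voxel_count"]], 1000)
  expect_equal(f2[["physical_size"]], 2000)

  sph <- sphere_mask(radius = 10)
  fs <- extract_features(sph)
  expect_lt(abs(fs[["equiv_sphere_radius"]] - 10) / 10, 0.02)
  # interior mask: no border contact
  expect_equal(fs[["border_surface_area"]], 0)
  expect_equal(fs[["border_voxel_count"]], 0)
  # elongation/flatness convention: both >= 1
  expect_gte(fs[["elongation"]], 1)
  expect_gte(fs[["flatness"]], 1)

  expect_error(extract_features(cube, feature_list = c("voxel_count", "bogus")),
               class = "config_error")
  expect_error(extract_features(brain_mask(array(0L, c(4, 4, 4)))),
               class = "empty_mask_error")
})

test_that("equivalent ellipsoid diameters recover the axes of an ellipsoid", {
  m <- generate_clean(mask_recipe(shape = c(48, 48, 48), spacing = c(2, 2, 2),
                                  semi_axes = c(30, 24, 18), axis_jitter = 0,
                                  center_jitter = 0, deform_amplitude = 0),
                      seed = 1)
  f <- extract_features(m)
  expect_lt(abs(f[["equiv_ellipsoid_diam_1"]] - 60) / 60, 0.03)
  expect_lt(abs(f[["equiv_ellipsoid_diam_2"]] - 48) / 48, 0.03)
  expect_lt(abs(f[["equiv_ellipsoid_diam_3"]] - 36) / 36, 0.03)
  expect_lt(abs(f[["feret_diameter"]] - 60) / 60, 0.03)
})

test_that("features are translation invariant except the centroid offsets", {
  m <- sphere_mask(radius = 6, dims = c(28L, 28L, 28L),
                   center = c(10, 10, 10))
  shifted <- brain_mask(maskqc:::shift1(maskqc:::shift1(m$voxels, 1, +1),
                                        3, +1),
                        spacing = m$spacing, id = "shifted")
  f0 <- extract_features(m)
  f1 <- extract_features(shifted)
  moving <- c("centroid_offset_1", "centroid_offset_2", "centroid_offset_3")
  keep <- setdiff(names(f0), moving)
  expect_equal(unclass(f0[keep]), unclass(f1[keep]), tolerance = 1e-9)
  expect_equal(f1[["border_surface_area"]], 0)
})

test_that("doubling spacing scales size, surface and radius as expected", {
  m1 <- sphere_mask(radius = 8, dims = c(24L, 24L, 24L))
  m2 <- brain_mask(m1$voxels, spacing = c(2, 2, 2), id = "scaled")
  f1 <- extract_features(m1)
  f2 <- extract_features(m2)
  expect_equal(f2[["voxel_count"]], f1[["voxel_count"]])
  expect_equal(f2[["physical_size"]], 8 * f1[["physical_size"]])
  expect_equal(f2[["surface_area"]], 4 * f1[["surface_area"]])
  expect_equal(f2[["equiv_sphere_radius"]], 2 * f1[["equiv_sphere_radius"]])
})

test_that("scaler: population convention, constant features, round trip", {
  x <- rbind(c(0, 5), c(2, 5))
  colnames(x) <- c("a", "b")
  sc <- fit_scaler(x)
  expect_equal(unname(sc$means), c(1, 5))
  expect_equal(unname(sc$stds), c(1, 1))   # population std; constant -> 1
  expect_true(sc$constant[["b"]])
  z <- apply_scaler(sc, x)
  expect_equal(unname(z[, "b"]), c(0, 0))

  set.seed(42)
  big <- matrix(rnorm(50 * 23, mean = 3, sd = 2), nrow = 50,
                dimnames = list(NULL, paste0("f", 1:23)))
  sc2 <- fit_scaler(big)
  z2 <- apply_scaler(sc2, big)
  expect_lt(max(abs(colMeans(z2))), 1e-10)
  expect_lt(max(abs(colMeans(z2^2) - 1)), 1e-10)

  v <- big[1, ]
  expect_equal(apply_scaler(sc2, sc2$means), setNames(rep(0, 23),
                                                      paste0("f", 1:23)))
  expect_equal(unname(apply_scaler(sc2, sc2$means + sc2$stds)), rep(1, 23))
  expect_equal(apply_scaler(sc2, v), (v - sc2$means) / sc2$stds)

  bad <- v
  names(bad) <- rev(names(v))
  expect_error(apply_scaler(sc2, bad), class = "config_error")
  expect_error(fit_scaler(big[1, , drop = FALSE]),
               class = "insufficient_data_error")
})
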