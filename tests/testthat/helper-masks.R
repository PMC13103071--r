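# Small mask builders and independent brute-force oracles shared by the
# unit and acceptance tests. Oracles are deliberately naive (triple
# loops, all-pairs scans) and never call the code paths they check.

cube_mask <- function(side = 10L, pad = 2L, spacing = c(1, 1, 1),
                      id = "cube") {
  n <- side + 2L * pad
  a <- array(0L, c(n, n, n))
  a[(pad + 1):(pad + side), (pad + 1):(pad + side),
    (pad + 1):(pad + side)] <- 1L
  brain_mask(a, spacing = spacing, id = id)
}

box_mask <- function(extents = c(20L, 10L, 10L), pad = 2L,
                     spacing = c(1, 1, 1), id = "box") {
  dims <- extents + 2L * pad
  a <- array(0L, dims)
  a[(pad + 1):(pad + extents[1]), (pad + 1):(pad + extents[2]),
    (pad + 1):(pad + extents[3])] <- 1L
  brain_mask(a, spacing = spacing, id = id)
}

sphere_mask <- function(radius = 10, dims = c(25L, 25L, 25L),
                        spacing = c(1, 1, 1), center = NULL, id = "sphere") {
  if (is.null(center)) center <- (dims - 1) / 2 * spacing
  co <- expand.grid(x = (seq_len(dims[1]) - 1) * spacing[1],
                    y = (seq_len(dims[2]) - 1) * spacing[2],
                    z = (seq_len(dims[3]) - 1) * spacing[3])
  inside <- (co$x - center[1])^2 + (co$y - center[2])^2 +
    (co$z - center[3])^2 <= radius^2
  brain_mask(array(as.integer(inside), dims), spacing = spacing, id = id)
}

# Random ellipsoid blob on a grid <= 32^3, optionally rotated by using
# anisotropic semi-axes and random center; always non-empty.
random_blob_mask <- function(seed, max_dim = 32L) {
  set.seed(seed)
  dims <- sample(10:max_dim, 3, replace = TRUE)
  spacing <- round(runif(3, 0.5, 2.5), 2)
  semi <- runif(3, 2, pmax(2.5, dims / 3)) * spacing
  center <- (dims - 1) / 2 * spacing + runif(3, -2, 2)
  co <- expand.grid(x = (seq_len(dims[1]) - 1) * spacing[1],
                    y = (seq_len(dims[2]) - 1) * spacing[2],
                    z = (seq_len(dims[3]) - 1) * spacing[3])
  inside <- ((co$x - center[1]) / semi[1])^2 +
    ((co$y - center[2]) / semi[2])^2 +
    ((co$z - center[3]) / semi[3])^2 <= 1
  if (!any(inside)) inside[which.min(rowSums(co^2))] <- TRUE
  brain_mask(array(as.integer(inside), dims), spacing = spacing,
             id = paste0("blob", seed))
}

# Naive triple-loop second central moments under the package's
# documented sign convention (variances on the diagonal, negated mixed
# products off it), in physical coordinates.
oracle_moments <- function(mask) {
  idx <- which(mask$voxels == 1L, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, mask$spacing, `*`)
  m <- nrow(pts)
  ctr <- colMeans(pts)
  M <- matrix(0, 3, 3)
  for (i in seq_len(m)) {
    d <- pts[i, ] - ctr
    for (a in 1:3) {
      for (b in 1:3) {
        M[a, b] <- M[a, b] + (if (a == b) 1 else -1) * d[a] * d[b]
      }
    }
  }
  M / m
}

oracle_dice <- function(a, b) {
  inter <- 0
  va <- a$voxels
  vb <- b$voxels
  for (i in seq_along(va)) inter <- inter + (va[i] == 1L && vb[i] == 1L)
  if (sum(va) + sum(vb) == 0) return(1)
  2 * inter / (sum(va) + sum(vb))
}

# All-pairs surface distances and HD95 on tiny grids. Surface voxels:
# foreground with a face-adjacent background neighbour (outside = bg).
oracle_surface_points <- function(mask) {
  a <- mask$voxels
  d <- dim(a)
  pts <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (a[i, j, k] == 1L) {
      nb <- c(if (i > 1) a[i - 1, j, k] else 0L,
              if (i < d[1]) a[i + 1, j, k] else 0L,
              if (j > 1) a[i, j - 1, k] else 0L,
              if (j < d[2]) a[i, j + 1, k] else 0L,
              if (k > 1) a[i, j, k - 1] else 0L,
              if (k < d[3]) a[i, j, k + 1] else 0L)
      if (any(nb == 0L)) pts <- rbind(pts, (c(i, j, k) - 1) * mask$spacing)
    }
  }
  pts
}

oracle_hd95 <- function(ma, mb) {
  pa <- oracle_surface_points(ma)
  pb <- oracle_surface_points(mb)
  directed <- function(p, q) {
    mins <- apply(p, 1, function(x) {
      sqrt(min(colSums((t(q) - x)^2)))
    })
    unname(quantile(mins, 0.95, type = 7))
  }
  max(directed(pa, pb), directed(pb, pa))
}

# Compact study conditions for fast unit tests: 48^3 grid at 2 mm.
small_recipe <- function(...) {
  mask_recipe(shape = c(48, 48, 48), spacing = c(2, 2, 2),
              semi_axes = c(30, 24, 22), ...)
}

small_site_recipes <- function() {
  list(mask_recipe(shape = c(48, 48, 48), spacing = c(2, 2, 2),
                   semi_axes = c(30, 24, 22)),
       mask_recipe(shape = c(48, 48, 48), spacing = c(2, 2, 2),
                   semi_axes = c(34, 27, 25)),
       mask_recipe(shape = c(48, 48, 48), spacing = c(2, 2, 2),
                   semi_axes = c(26, 21, 19)))
}

# Gaussian blobs with planted cluster structure (centers mutually
# `sep` apart in Euclidean distance).
blob_features <- function(k, n_per, sep = 10, sigma = 0.1, seed = 1,
                          p = 5) {
  set.seed(seed)
  centers <- matrix(0, k, p)
  for (i in seq_len(k)) centers[i, ] <- (i - 1) * sep / sqrt(p)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(matrix(rnorm(n_per * p, sd = sigma), n_per, p), 2,
          centers[i, ], `+`)
  }))
  colnames(x) <- paste0("f", seq_len(p))
  x
}

# Hand-built cluster set with identity covariances, for closed-form
# distance checks.
identity_cluster_set <- function(centers, sizes) {
  k <- nrow(centers)
  p <- ncol(centers)
  structure(list(k = k, sizes = sizes, means = centers,
                 covs = replicate(k, diag(p), simplify = FALSE),
                 inv_covs = replicate(k, diag(p), simplify = FALSE),
                 shrinkages = rep(0, k),
                 assignment = rep(seq_len(k), times = sizes)),
            class = "cluster_set")
}

# The end-to-end synthetic screen at the package's study conditions is
# expensive; build it once per test run and memoize.
.screen_cache <- new.env(parent = emptyenv())

end_to_end_screen <- function() {
  if (!is.null(.screen_cache$result)) return(.screen_cache$result)
  root <- file.path(tempdir(), "maskqc-screen")
  baseline_dir <- file.path(root, "baseline")
  test_dir <- file.path(root, "test")
  generate_cohort(baseline_dir, n_clean = 60L, n_corrupt = 0L, seed = 17L)
  manifest <- generate_cohort(test_dir, n_clean = 40L, n_corrupt = 40L,
                              seed = 1017L)
  cfg <- qc_config()
  model <- fit_baseline(feature_table(read_mask_dir(baseline_dir)), cfg)
  scores <- score_masks(read_mask_dir(test_dir), model)
  merged <- merge(scores, manifest, by = "mask_id")
  self_scores <- score_masks(read_mask_dir(baseline_dir), model)
  .screen_cache$result <- list(
    model = model,
    scores = scores,
    merged = merged,
    confusion = confusion_summary(merged),
    self_pass_rate = mean(self_scores$verdict == "pass"),
    baseline_dir = baseline_dir,
    test_dir = test_dir)
  .screen_cache$result
}
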