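test_that("Rand index agrees with an independent implementation", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  skip_if_not_installed("e1071")
  set.seed(7)
  for (i in 1:10) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(rand_index(a, b),
                 e1071::classAgreement(table(a, b))$rand)
  }
})

test_that("stability selection recovers planted cluster counts", {
  x3 <- blob_features(3, 20, seed = 5)
  rep3 <- select_k(x3, k_range = 2:6, runs = 20, seed = 11, max_pairs = 60)
  expect_equal(rep3$chosen_k, 3L)
  expect_gte(max(rep3$table$mean_rand_index), 0.95)

  x2 <- blob_features(2, 25, seed = 6)
  rep2 <- select_k(x2, k_range = 2:6, runs = 20, seed = 12, max_pairs = 60)
  expect_equal(rep2$chosen_k, 2L)
})

test_that("degenerate clustering inputs raise classed errors", {
  x <- matrix(1 + rnorm(60 * 4, sd = 1e-13), 60, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  expect_error(select_k(x, k_range = 2:4, runs = 5, seed = 1),
               class = "degenerate_clustering_error")
  small <- blob_features(2, 3, seed = 1)   # 6 points, k up to 10
  expect_error(select_k(small, k_range = 2:10, runs = 5, seed = 1),
               class = "degenerate_clustering_error")
})

test_that("covariance shrinkage keeps estimates invertible and consistent", {
  set.seed(3)
  # fewer members than features: plain covariance is singular
  x <- matrix(rnorm(8 * 23), 8, 23)
  sh <- maskqc:::shrink_covariance(x)
  expect_equal(sh$cov, t(sh$cov), tolerance = 1e-12)
  inv <- maskqc:::invert_covariance(sh$cov)
  expect_lt(max(abs(inv %*% sh$cov - diag(23))), 1e-6)
  # large sample of spherical data: shrinkage target matches the truth
  y <- matrix(rnorm(5000 * 4), 5000, 4)
  shy <- maskqc:::shrink_covariance(y)
  expect_lt(max(abs(shy$cov - diag(4))), 0.1)
})

test_that("percentile thresholds follow linear interpolation", {
  # engineered distances: v = (d, 0, ...) from a cluster at the origin
  # with identity covariance gives d_min = |d|
  cs <- identity_cluster_set(matrix(0, 1, 2), sizes = 10L)
  z <- cbind(1:10, 0)
  thr <- score_baseline_thresholds(z, cs, percentile = 90)
  expect_equal(thr$t_min, 9.1)               # 90th pct of {1..10}
  expect_equal(thr$d_min, as.numeric(1:10))
  # d_bar for k = 1 is d_min / |C_1|
  expect_equal(thr$d_bar, (1:10) / 10)
  # constant distance set: threshold equals the constant at any n
  zc <- cbind(rep(4, 6), 0)
  thr_c <- score_baseline_thresholds(zc, cs, percentile = 37)
  expect_equal(thr_c$t_min, 4)
  # n = 50 gives the median
  thr_m <- score_baseline_thresholds(z, cs, percentile = 50)
  expect_equal(thr_m$t_min, median(1:10))
  expect_error(score_baseline_thresholds(z, cs, percentile = 101),
               class = "config_error")
})

test_that("fit_baseline recovers planted structure and is deterministic", {
  x <- blob_features(2, 30, sep = 12, sigma = 0.5, seed = 9, p = 6)
  cfg <- qc_config(k_min = 2, k_max = 5, runs = 20, max_pairs = 60,
                   seed = 33, feature_list = feature_catalogue(),
                   min_baseline = 30)
  m1 <- fit_baseline(x, cfg)
  expect_equal(m1$clusters$k, 2L)
  expect_gt(m1$t_min, 0)
  expect_gt(m1$t_mu, 0)
  # cluster means near the planted centers (in normalized space, the two
  # clusters are symmetric about 0)
  expect_equal(sort(m1$clusters$sizes), c(30L, 30L))
  expect_lt(max(abs(m1$clusters$means[1, ] + m1$clusters$means[2, ])), 0.5)
  # determinism: identical inputs + seed give an identical model
  m2 <- fit_baseline(x, cfg)
  expect_identical(m1$clusters$assignment, m2$clusters$assignment)
  expect_identical(m1$t_min, m2$t_min)
  expect_identical(m1$clusters$means, m2$clusters$means)

  expect_error(fit_baseline(x[1:10, ], cfg),
               class = "insufficient_data_error")
})

test_that("threshold coverage: ~10% of baseline exceeds t_min at n = 90", {
  x <- blob_features(2, 30, sep = 12, sigma = 0.5, seed = 10, p = 6)
  cfg <- qc_config(k_min = 2, k_max = 4, runs = 15, max_pairs = 40,
                   seed = 5)
  model <- fit_baseline(x, cfg)
  frac <- mean(model$baseline_d_min > model$t_min)
  expect_lte(frac, 0.10 + 1 / nrow(x))
})

test_that("model JSON round trip reproduces scores", {
  x <- blob_features(2, 20, sep = 8, sigma = 0.4, seed = 21, p = 4)
  cfg <- qc_config(k_min = 2, k_max = 3, runs = 10, max_pairs = 20,
                   seed = 2, min_baseline = 30)
  model <- fit_baseline(x, cfg)
  path <- tempfile(fileext = ".json")
  write_model(model, path)
  model2 <- read_model(path)
  expect_equal(model2$t_min, model$t_min)
  expect_equal(model2$clusters$means, model$clusters$means,
               tolerance = 1e-12)
  v <- apply_scaler(model$scaler, x[7, ])
  d1 <- distance_stats(v, model$clusters)
  d2 <- distance_stats(apply_scaler(model2$scaler, x[7, ]),
                       model2$clusters)
  expect_equal(d1$d_min, d2$d_min, tolerance = 1e-10)
  expect_equal(d1$d_bar, d2$d_bar, tolerance = 1e-10)
  expect_error(read_model(tempfile()), class = "config_error")
})
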