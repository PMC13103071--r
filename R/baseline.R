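#' Rand index between two partitions
#'
#' Plain (unadjusted) Rand index: the fraction of item pairs on which
#' two partitions of the same items agree (both together or both apart).
#'
#' @param a,b Integer/factor vectors of equal length with cluster labels.
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) config_error("partitions must have equal length")
  n <- length(a)
  if (n < 2L) config_error("Rand index needs at least 2 items")
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_i - sum_j) / total
}

#' Select the number of k-means clusters by Rand-index stability
#'
#' For each candidate k, runs `runs` k-means fits from distinct seeded
#' initializations and computes the mean pairwise Rand index between the
#' resulting partitions over a seeded subsample of run pairs. The k with
#' the highest mean Rand index (ties broken toward the smallest k) is
#' selected. Deterministic given `seed`.
#'
#' @param x Numeric matrix of normalized feature vectors (rows = masks).
#' @param k_range Integer vector of candidate cluster counts (default 2:10).
#' @param runs Number of k-means restarts per k (default 500).
#' @param seed Integer seed driving all initializations and pair sampling.
#' @param max_pairs Maximum number of run pairs scored per k (default 500).
#' @return An object of class `k_selection`: `chosen_k`, `table`
#'   (data.frame of k and mean Rand index), `runs`, `seed`.
#' @export
select_k <- function(x, k_range = 2:10, runs = 500L, seed = 1L,
                     max_pairs = 500L) {
  x <- as_feature_matrix(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (nrow(x) <= max(k_range)) {
    degenerate_clustering_error(sprintf(
      "need more than %d points to cluster with k up to %d",
      max(k_range), max(k_range)))
  }
  if (runs < 2L) config_error("`runs` must be at least 2")
  if (max(apply(x, 2, stats::sd)) < 1e-10) {
    degenerate_clustering_error(
      "feature vectors are numerically identical; baseline is degenerate")
  }
  run_seeds <- with_seed(seed, matrix(
    sample.int(.Machine$integer.max - 1L, runs * length(k_range)),
    nrow = runs))
  mean_ri <- numeric(length(k_range))
  for (j in seq_along(k_range)) {
    k <- k_range[j]
    parts <- matrix(0L, nrow = nrow(x), ncol = runs)
    for (r in seq_len(runs)) {
      parts[, r] <- kmeans_run(x, k, run_seeds[r, j])$cluster
    }
    all_pairs <- utils::combn(runs, 2)
    if (ncol(all_pairs) > max_pairs) {
      keep <- with_seed(seed + j, sample.int(ncol(all_pairs), max_pairs))
      all_pairs <- all_pairs[, keep, drop = FALSE]
    }
    mean_ri[j] <- mean(vapply(seq_len(ncol(all_pairs)), function(p) {
      rand_index(parts[, all_pairs[1, p]], parts[, all_pairs[2, p]])
    }, numeric(1)))
  }
  chosen <- k_range[which.max(mean_ri)]   # ties -> smallest k (first max)
  structure(list(chosen_k = chosen,
                 table = data.frame(k = k_range, mean_rand_index = mean_ri),
                 runs = runs, seed = seed),
            class = "k_selection")
}

# k-means++ seeding: spread the initial centers with probability
# proportional to the squared distance from the centers already chosen.
# Plain random-row initialization sticks in poor local optima on tightly
# clustered data, which corrupts the stability signal.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ], `-`)^2)
  for (i in seq_len(k - 1L)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i + 1L, ] <- x[sample.int(n, 1, prob = prob), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[i + 1L, ], `-`)^2))
  }
  centers
}

# One seeded k-means fit from a k-means++ initialization; Lloyd fallback
# for the rare degenerate starts Hartigan-Wong rejects.
kmeans_run <- function(x, k, seed) {
  with_seed(seed, {
    centers <- kmeanspp_centers(x, k)
    tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers,
                                     iter.max = 100L)),
      error = function(e) suppressWarnings(
        stats::kmeans(x, centers = k, iter.max = 100L,
                      algorithm = "Lloyd")))
  })
}

# Ledoit-Wolf-style shrinkage of a sample covariance toward a scaled
# identity; keeps the estimate well conditioned when cluster membership
# is smaller than the feature dimension. `floor` is the minimum
# shrinkage intensity applied even to well-determined clusters.
shrink_covariance <- function(x, floor = 1e-6) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  xc <- sweep(x, 2, colMeans(x), `-`)
  s <- crossprod(xc) / n
  mu <- sum(diag(s)) / p
  d2 <- sum((s - diag(mu, p))^2)
  if (d2 < .Machine$double.eps) {
    shrink <- 1
  } else {
    b2bar <- sum(vapply(seq_len(n), function(i) {
      sum((tcrossprod(xc[i, ]) - s)^2)
    }, numeric(1))) / n^2
    shrink <- min(1, b2bar / d2)
  }
  shrink <- max(shrink, floor)
  cov <- shrink * diag(mu, p) + (1 - shrink) * s
  list(cov = cov, shrinkage = shrink, target_scale = mu)
}

invert_covariance <- function(cov) {
  inv <- tryCatch(solve(cov), error = function(e) NULL)
  if (is.null(inv) || any(!is.finite(inv))) inv <- MASS::ginv(cov)
  (inv + t(inv)) / 2
}

#' Percentile thresholds of the baseline distance distributions
#'
#' Scores every baseline vector against the fitted clusters, collects
#' the sets of minimum and weighted-mean Mahalanobis distances, and
#' returns their nth percentiles (linear interpolation between order
#' statistics) as the thresholds `t_min` and `t_mu`.
#'
#' @param z Normalized baseline feature matrix.
#' @param clusters A cluster set as stored in a [fit_baseline()] model.
#' @param percentile Percentile n in (0, 100); default 90.
#' @param d_bar_mode Aggregation rule for the mean distance, see
#'   [distance_stats()].
#' @return List with `t_min`, `t_mu`, and the baseline distance sets
#'   `d_min`, `d_bar`.
#' @export
score_baseline_thresholds <- function(z, clusters, percentile = 90,
                                      d_bar_mode = "as_printed") {
  if (percentile <= 0 || percentile >= 100) {
    config_error("`percentile` must lie strictly between 0 and 100")
  }
  stats_list <- apply(z, 1, distance_stats, clusters = clusters,
                      d_bar_mode = d_bar_mode, simplify = FALSE)
  d_min <- vapply(stats_list, `[[`, numeric(1), "d_min")
  d_bar <- vapply(stats_list, `[[`, numeric(1), "d_bar")
  list(t_min = unname(stats::quantile(d_min, percentile / 100, type = 7)),
       t_mu = unname(stats::quantile(d_bar, percentile / 100, type = 7)),
       d_min = unname(d_min), d_bar = unname(d_bar))
}

#' Fit the baseline QC model on a ground-truth cohort
#'
#' Normalizes the baseline features (zero mean, unit variance), selects
#' the cluster count k by Rand-index stability ([select_k()]), takes the
#' restart with the lowest within-cluster sum of squares at the chosen k
#' as the final clustering, stores per-cluster mean, shrinkage-
#' regularized covariance and its inverse, and derives the percentile
#' thresholds `t_min` and `t_mu` from the baseline's own distances.
#' Clusters that end up with a single member trigger a refit at k - 1
#' (down to k = 2).
#'
#' @param features Feature table ([feature_table()] data.frame) or
#'   numeric matrix of raw (unnormalized) baseline features.
#' @param config A [qc_config()]; controls k range, restarts, percentile,
#'   seed, shrinkage floor and distance mode.
#' @return An object of class `baseline_model`.
#' @export
fit_baseline <- function(features, config = qc_config()) {
  x <- as_feature_matrix(features)
  if (nrow(x) < config$min_baseline) {
    insufficient_data_error(sprintf(
      "baseline has %d masks; at least %d required", nrow(x),
      config$min_baseline))
  }
  scaler <- fit_scaler(x)
  z <- apply_scaler(scaler, x)
  k_report <- select_k(z, k_range = config$k_min:config$k_max,
                       runs = config$runs, seed = config$seed,
                       max_pairs = config$max_pairs)
  k <- k_report$chosen_k
  final <- NULL
  repeat {
    final <- best_kmeans(z, k, runs = config$runs, seed = config$seed)
    if (min(tabulate(final$cluster, k)) >= 2L) break
    k <- k - 1L
    if (k < 2L) {
      degenerate_clustering_error(
        "no k >= 2 yields clusters with at least 2 members")
    }
  }
  clusters <- build_cluster_set(z, final$cluster, k,
                                floor = config$shrinkage_floor)
  thr <- score_baseline_thresholds(z, clusters,
                                   percentile = config$percentile,
                                   d_bar_mode = config$d_bar_mode)
  structure(list(scaler = scaler,
                 clusters = clusters,
                 t_min = thr$t_min,
                 t_mu = thr$t_mu,
                 baseline_d_min = thr$d_min,
                 baseline_d_bar = thr$d_bar,
                 k_report = k_report,
                 config = config),
            class = "baseline_model")
}

# Restart with the lowest within-cluster sum of squares among `runs`
# seeded fits at a fixed k.
best_kmeans <- function(z, k, runs, seed) {
  run_seeds <- with_seed(seed + 104729L, # offset so final fits reuse no
                                         # selection-stage streams
                         sample.int(.Machine$integer.max - 1L, runs))
  best <- NULL
  for (r in seq_len(runs)) {
    fit <- kmeans_run(z, k, run_seeds[r])
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

build_cluster_set <- function(z, assignment, k, floor = 1e-6) {
  sizes <- tabulate(assignment, k)
  means <- matrix(0, nrow = k, ncol = ncol(z),
                  dimnames = list(NULL, colnames(z)))
  covs <- vector("list", k)
  inv_covs <- vector("list", k)
  shrinkages <- numeric(k)
  for (i in seq_len(k)) {
    zi <- z[assignment == i, , drop = FALSE]
    means[i, ] <- colMeans(zi)
    sh <- shrink_covariance(zi, floor = floor)
    covs[[i]] <- sh$cov
    inv_covs[[i]] <- invert_covariance(sh$cov)
    shrinkages[i] <- sh$shrinkage
  }
  structure(list(k = k, sizes = sizes, means = means, covs = covs,
                 inv_covs = inv_covs, shrinkages = shrinkages,
                 assignment = assignment),
            class = "cluster_set")
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf(paste0("<baseline_model> %d masks, k = %d clusters ",
                     "(sizes %s)\n  t_min = %.4g, t_mu = %.4g ",
                     "(percentile %g)\n"),
              length(x$clusters$assignment), x$clusters$k,
              paste(x$clusters$sizes, collapse = "/"),
              x$t_min, x$t_mu, x$config$percentile))
  invisible(x)
}

#' Save / load a fitted baseline model
#'
#' The model is serialized as a single JSON sidecar holding the scaler
#' statistics, per-cluster parameters, thresholds, config snapshot and
#' version metadata; it can be reloaded for scoring without access to
#' the baseline masks.
#'
#' @param model A [fit_baseline()] result.
#' @param path Output JSON path.
#' @return `path` invisibly (`write_model`); a `baseline_model`
#'   (`read_model`).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "baseline_model"))
  payload <- list(
    format = "maskqc-baseline-model",
    version = as.character(utils::packageVersion("maskqc")),
    r_version = R.version.string,
    scaler = list(means = model$scaler$means,
                  stds = model$scaler$stds,
                  constant = model$scaler$constant,
                  feature_names = model$scaler$feature_names),
    clusters = list(k = model$clusters$k,
                    sizes = model$clusters$sizes,
                    means = model$clusters$means,
                    covs = model$clusters$covs,
                    shrinkages = model$clusters$shrinkages,
                    assignment = model$clusters$assignment),
    t_min = model$t_min,
    t_mu = model$t_mu,
    baseline_d_min = model$baseline_d_min,
    baseline_d_bar = model$baseline_d_bar,
    k_table = model$k_report$table,
    chosen_k = model$k_report$chosen_k,
    config = unclass(model$config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) {
    config_error(sprintf("model file not found: %s", path))
  }
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "maskqc-baseline-model")) {
    config_error(sprintf("%s is not a maskqc model file", path))
  }
  scaler <- structure(list(
    means = stats::setNames(as.numeric(p$scaler$means),
                            p$scaler$feature_names),
    stds = stats::setNames(as.numeric(p$scaler$stds),
                           p$scaler$feature_names),
    constant = as.logical(p$scaler$constant),
    feature_names = p$scaler$feature_names), class = "feature_scaler")
  k <- p$clusters$k
  covs_raw <- p$clusters$covs
  covs <- lapply(seq_len(k), function(i) {
    m <- if (is.array(covs_raw) && length(dim(covs_raw)) == 3) {
      covs_raw[i, , ]       # jsonlite simplifies a list of matrices
    } else {
      as.matrix(covs_raw[[i]])
    }
    storage.mode(m) <- "double"
    m
  })
  means <- as.matrix(p$clusters$means)
  colnames(means) <- p$scaler$feature_names
  clusters <- structure(list(
    k = k, sizes = as.integer(p$clusters$sizes), means = means,
    covs = covs, inv_covs = lapply(covs, invert_covariance),
    shrinkages = as.numeric(p$clusters$shrinkages),
    assignment = as.integer(p$clusters$assignment)),
    class = "cluster_set")
  cfg <- do.call(qc_config, p$config[names(p$config) %in%
                                       names(formals(qc_config))])
  structure(list(scaler = scaler, clusters = clusters,
                 t_min = p$t_min, t_mu = p$t_mu,
                 baseline_d_min = as.numeric(p$baseline_d_min),
                 baseline_d_bar = as.numeric(p$baseline_d_bar),
                 k_report = structure(list(chosen_k = p$chosen_k,
                                           table = p$k_table,
                                           runs = cfg$runs,
                                           seed = cfg$seed),
                                      class = "k_selection"),
                 config = cfg),
            class = "baseline_model")
}
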