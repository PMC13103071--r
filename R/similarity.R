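#' Mahalanobis distance of a point from a cluster
#'
#' `sqrt((x - center)' S^-1 (x - center))` with a precomputed inverse
#' covariance; tiny negative round-off under the square root is clipped
#' to zero.
#'
#' @param x Numeric vector.
#' @param center Cluster mean, same length as `x`.
#' @param inv_cov Symmetric positive semidefinite inverse covariance.
#' @return Non-negative scalar distance.
#' @export
mahalanobis_distance <- function(x, center, inv_cov) {
  if (length(x) != length(center) ||
      !all(dim(inv_cov) == c(length(x), length(x)))) {
    config_error("dimension mismatch in Mahalanobis distance")
  }
  d <- as.numeric(x) - as.numeric(center)
  sqrt(max(0, sum(d * (inv_cov %*% d))))
}

#' Distance statistics of a vector against the baseline clusters
#'
#' Computes the Mahalanobis distance of `v` to each cluster, the minimum
#' distance `d_min`, and the aggregate `d_bar`. The default `d_bar` is
#' the inverse-size-weighted sum `sum_i d_i / |C_i|` (small clusters
#' dominate); `"size_weighted"` gives the conventional weighted mean
#' `sum_i |C_i| d_i / sum_i |C_i|`, and `"median"` the median per-cluster
#' distance.
#'
#' @param v Normalized feature vector.
#' @param clusters A `cluster_set` from a fitted [fit_baseline()] model.
#' @param d_bar_mode One of `"as_printed"`, `"size_weighted"`, `"median"`.
#' @return List with `d_min`, `d_bar`, `per_cluster`.
#' @export
distance_stats <- function(v, clusters,
                           d_bar_mode = c("as_printed", "size_weighted",
                                          "median")) {
  d_bar_mode <- match.arg(d_bar_mode)
  k <- clusters$k
  per <- vapply(seq_len(k), function(i) {
    mahalanobis_distance(v, clusters$means[i, ], clusters$inv_covs[[i]])
  }, numeric(1))
  d_bar <- switch(d_bar_mode,
    as_printed = sum(per / clusters$sizes),
    size_weighted = sum(clusters$sizes * per) / sum(clusters$sizes),
    median = stats::median(per))
  list(d_min = min(per), d_bar = d_bar, per_cluster = per)
}

#' Similarity score r
#'
#' Combines the threshold-normalized minimum and mean distances into a
#' bounded similarity score:
#' `r = (2/pi) * atan(gamma * d_min/t_min + (1 - gamma) * d_bar/t_mu)`.
#' With the default normalized constant, r lies in `[0, 1)` and a mask
#' sitting exactly at both thresholds scores exactly 0.5, which is what
#' makes the default cutoff `r_max = 0.5` meaningful. The `"literal"`
#' mode uses a `pi/2` leading constant instead (range `[0, pi^2/4)`).
#'
#' @param d_min,d_bar Distance statistics of the vector under test.
#' @param t_min,t_mu Positive baseline thresholds.
#' @param gamma Weight in `[0, 1]` on the local (minimum-distance) term;
#'   default 0.75.
#' @param constant `"normalized"` (default, `2/pi`) or `"literal"`
#'   (`pi/2`).
#' @return The similarity score r.
#' @export
#' @examples
#' similarity_r(1, 1, 1, 1, gamma = 0.75)  # exactly 0.5
similarity_r <- function(d_min, d_bar, t_min, t_mu, gamma = 0.75,
                         constant = c("normalized", "literal")) {
  constant <- match.arg(constant)
  if (!is.finite(t_min) || !is.finite(t_mu) || t_min <= 0 || t_mu <= 0) {
    config_error("thresholds t_min and t_mu must be strictly positive")
  }
  if (gamma < 0 || gamma > 1) config_error("`gamma` must lie in [0, 1]")
  arg <- gamma * d_min / t_min + (1 - gamma) * d_bar / t_mu
  scale <- if (constant == "normalized") 2 / pi else pi / 2
  scale * atan(arg)
}

#' Pass/fail verdict at a cutoff
#'
#' A mask passes QC exactly when its similarity score does not exceed
#' `r_max` (the boundary `r == r_max` passes).
#'
#' @param r Similarity score(s).
#' @param r_max Cutoff, default 0.5.
#' @return Character vector `"pass"`/`"fail"`.
#' @export
classify_verdict <- function(r, r_max = 0.5) {
  ifelse(r <= r_max, "pass", "fail")
}

#' Score one mask against a fitted baseline
#'
#' @param mask A [brain_mask].
#' @param model A [fit_baseline()] model.
#' @return List of class `qc_score`: `mask_id`, `d_min`, `d_bar`, `r`,
#'   `verdict`, `per_cluster_distances`.
#' @export
qc_score <- function(mask, model) {
  stopifnot(inherits(model, "baseline_model"))
  cfg <- model$config
  f <- extract_features(mask, feature_list = cfg$feature_list)
  v <- apply_scaler(model$scaler, f)
  ds <- distance_stats(v, model$clusters, d_bar_mode = cfg$d_bar_mode)
  r <- similarity_r(ds$d_min, ds$d_bar, model$t_min, model$t_mu,
                    gamma = cfg$gamma, constant = cfg$arctan_constant)
  structure(list(mask_id = mask$id, d_min = ds$d_min, d_bar = ds$d_bar,
                 r = r, verdict = classify_verdict(r, cfg$r_max),
                 per_cluster_distances = ds$per_cluster),
            class = "qc_score")
}

#' Score a batch of masks
#'
#' Per-mask failures (e.g. an empty mask) are recorded in the `error`
#' column of the returned table instead of aborting the batch.
#'
#' @param masks List of [brain_mask] objects.
#' @param model A [fit_baseline()] model.
#' @return Data.frame with columns `mask_id`, `d_min`, `d_bar`, `r`,
#'   `verdict`, `error`.
#' @export
score_masks <- function(masks, model) {
  rows <- lapply(masks, function(m) {
    tryCatch({
      s <- qc_score(m, model)
      data.frame(mask_id = s$mask_id, d_min = s$d_min, d_bar = s$d_bar,
                 r = s$r, verdict = s$verdict, error = NA_character_)
    }, maskqc_error = function(e) {
      data.frame(mask_id = m$id, d_min = NA_real_, d_bar = NA_real_,
                 r = NA_real_, verdict = NA_character_,
                 error = paste(class(e)[1], conditionMessage(e), sep = ": "))
    })
  })
  do.call(rbind, rows)
}
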