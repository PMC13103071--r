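#' Quality-control configuration
#'
#' Gathers every tunable parameter of the method; the defaults are the
#' package's operating point: gamma = 0.75, 90th-percentile thresholds,
#' r_max = 0.5, k searched over 2..10 with 500 clustering restarts.
#'
#' @param gamma Weight on the minimum-distance (local) term in
#'   [similarity_r()], in `[0, 1]`.
#' @param percentile Percentile n in (0, 100) used for `t_min`/`t_mu`.
#' @param r_max Pass/fail cutoff on r.
#' @param k_min,k_max Inclusive k-means cluster-count search range.
#' @param runs Clustering restarts per candidate k.
#' @param arctan_constant `"normalized"` (2/pi, r in `[0,1)`) or
#'   `"literal"` (pi/2).
#' @param d_bar_mode `"as_printed"`, `"size_weighted"`, or `"median"`;
#'   see [distance_stats()].
#' @param feature_list Feature names used throughout, see
#'   [feature_catalogue()].
#' @param seed Integer seed for every random choice in fitting.
#' @param min_baseline Minimum baseline cohort size (default 30).
#' @param shrinkage_floor Minimum covariance shrinkage intensity.
#' @param max_pairs Run pairs sampled per k in [select_k()].
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(gamma = 0.75, percentile = 90, r_max = 0.5,
                      k_min = 2L, k_max = 10L, runs = 500L,
                      arctan_constant = c("normalized", "literal"),
                      d_bar_mode = c("as_printed", "size_weighted",
                                     "median"),
                      feature_list = feature_catalogue(), seed = 17L,
                      min_baseline = 30L, shrinkage_floor = 1e-6,
                      max_pairs = 500L) {
  arctan_constant <- match.arg(arctan_constant)
  d_bar_mode <- match.arg(d_bar_mode)
  if (gamma < 0 || gamma > 1) config_error("`gamma` must lie in [0, 1]")
  if (percentile <= 0 || percentile >= 100) {
    config_error("`percentile` must lie strictly between 0 and 100")
  }
  if (r_max < 0) config_error("`r_max` must be non-negative")
  if (k_min < 2 || k_max < k_min) {
    config_error("need 2 <= k_min <= k_max")
  }
  if (runs < 2) config_error("`runs` must be at least 2")
  unknown <- setdiff(feature_list, feature_catalogue(default = FALSE))
  if (length(unknown) > 0) {
    config_error(paste0("unknown feature name(s): ",
                        paste(unknown, collapse = ", ")))
  }
  structure(list(gamma = gamma, percentile = percentile, r_max = r_max,
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 runs = as.integer(runs),
                 arctan_constant = arctan_constant,
                 d_bar_mode = d_bar_mode, feature_list = feature_list,
                 seed = as.integer(seed),
                 min_baseline = as.integer(min_baseline),
                 shrinkage_floor = shrinkage_floor,
                 max_pairs = as.integer(max_pairs)),
            class = "qc_config")
}

#' Read / write a QC configuration file
#'
#' Human-editable YAML with every algorithm parameter surfaced; the
#' round trip through the file is lossless.
#'
#' @param path YAML file path.
#' @param config A [qc_config()].
#' @return `read_config`: a `qc_config`; `write_config`: `path`
#'   invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    config_error(sprintf("config file not found: %s", path))
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(qc_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    config_error(paste0("unknown config key(s): ",
                        paste(extra, collapse = ", ")))
  }
  do.call(qc_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "qc_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full QC pipeline
#'
#' Fits the baseline model on the masks in `baseline_dir`, scores the
#' masks in `test_dir`, and — when ground-truth pairs are provided —
#' evaluates verdicts against the sanity labels. Writes `scores.csv`,
#' optionally `eval.csv` and `summary.json`, plus `model.json` and a
#' `run_log.txt` with the config snapshot, into `out_dir`.
#'
#' @param config A [qc_config()].
#' @param baseline_dir Directory of baseline (ground-truth) masks.
#' @param test_dir Directory of candidate masks to score.
#' @param out_dir Output directory (created if missing).
#' @param gt_pairs Optional data.frame with columns `candidate` and
#'   `ground_truth` (file names inside `test_dir`/`baseline_dir` or
#'   full paths) plus optional grouping columns carried into the
#'   pass-rate table.
#' @return Invisibly, a list with `model`, `scores`, and (when pairs are
#'   given) `eval` and `summary`.
#' @export
run_pipeline <- function(config, baseline_dir, test_dir, out_dir,
                         gt_pairs = NULL) {
  stopifnot(inherits(config, "qc_config"))
  baseline_masks <- read_mask_dir(baseline_dir)
  if (length(baseline_masks) == 0) {
    maskqc_error("data_error",
                 sprintf("baseline directory %s contains no masks",
                         baseline_dir))
  }
  test_masks <- read_mask_dir(test_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  feats <- feature_table(baseline_masks, config$feature_list)
  model <- fit_baseline(feats, config)
  write_model(model, file.path(out_dir, "model.json"))

  scores <- score_masks(test_masks, model)
  utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)

  result <- list(model = model, scores = scores)
  if (!is.null(gt_pairs)) {
    resolve <- function(name, dir) {
      ifelse(file.exists(name), name, file.path(dir, name))
    }
    cand <- lapply(resolve(gt_pairs$candidate, test_dir), read_mask)
    gt <- lapply(resolve(gt_pairs$ground_truth, baseline_dir), read_mask)
    eval_df <- evaluate_masks(cand, gt, model)
    group_cols <- setdiff(names(gt_pairs), c("candidate", "ground_truth"))
    for (g in group_cols) eval_df[[g]] <- gt_pairs[[g]]
    utils::write.csv(eval_df, file.path(out_dir, "eval.csv"),
                     row.names = FALSE)
    summ <- confusion_summary(eval_df)
    rates <- pass_rate_table(eval_df, group_cols)
    jsonlite::write_json(list(confusion = unclass(summ),
                              pass_rates = rates),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result$eval <- eval_df
    result$summary <- summ
    result$pass_rates <- rates
  }
  writeLines(c(sprintf("maskqc %s run at %s",
                       as.character(utils::packageVersion("maskqc")),
                       format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               sprintf("baseline_dir: %s (%d masks)", baseline_dir,
                       length(baseline_masks)),
               sprintf("test_dir: %s (%d masks)", test_dir,
                       length(test_masks)),
               sprintf("chosen_k: %d", model$clusters$k),
               sprintf("t_min: %.10g  t_mu: %.10g", model$t_min,
                       model$t_mu),
               "config:",
               yaml::as.yaml(unclass(config))),
             file.path(out_dir, "run_log.txt"))
  invisible(result)
}

#' Compare a cohort's similarity-score distribution to a baseline
#'
#' Scores every mask of a held-out cohort against a fitted model and
#' summarizes the r distribution — the out-of-distribution screening
#' use of the method (a cohort resembling the baseline concentrates
#' below the cutoff; a shifted cohort drifts upward).
#'
#' @param model A [fit_baseline()] model.
#' @param cohort Non-empty list of [brain_mask] objects.
#' @return List of class `cohort_comparison`: `r` (per-mask scores),
#'   `n`, `median_r`, `mean_r`, `quantiles` (5/25/50/75/95%), and
#'   `pass_rate` at the model's r_max.
#' @export
compare_cohorts <- function(model, cohort) {
  stopifnot(inherits(model, "baseline_model"))
  if (length(cohort) == 0) {
    insufficient_data_error("cohort is empty")
  }
  scores <- score_masks(cohort, model)
  r <- scores$r[!is.na(scores$r)]
  if (length(r) == 0) {
    insufficient_data_error("no cohort mask could be scored")
  }
  structure(list(r = scores$r, n = nrow(scores),
                 median_r = stats::median(r), mean_r = mean(r),
                 quantiles = stats::quantile(r, c(.05, .25, .5, .75, .95)),
                 pass_rate = mean(r <= model$config$r_max)),
            class = "cohort_comparison")
}
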