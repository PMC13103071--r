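check_same_grid <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9) {
    grid_mismatch_error("masks must share grid shape and spacing")
  }
}

#' Dice similarity coefficient of two masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks agree perfectly (Dice 1);
#' one empty mask against a non-empty one scores 0.
#'
#' @param a,b [brain_mask] objects on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_same_grid(a, b)
  na <- sum(a$voxels)
  nb <- sum(b$voxels)
  if (na + nb == 0L) return(1)
  2 * sum(a$voxels == 1L & b$voxels == 1L) / (na + nb)
}

# Directed nearest-surface distances from point set pa to pb (mm),
# exact; the heavy all-pairs scan runs in compiled code.
nearest_distances <- function(pa, pb) {
  nearest_distances_cpp(pa, pb)
}

#' 95th-percentile Hausdorff distance between two masks
#'
#' Surfaces are the foreground voxels with at least one face-adjacent
#' background neighbour (6-connectivity, grid boundary counts as
#' background). Each directed distance is the 95th percentile (linear
#' interpolation) of the nearest-surface distances from one surface to
#' the other, in mm via the voxel spacing; the reported HD95 is the
#' maximum of the two directions.
#'
#' @param a,b Non-empty [brain_mask] objects on the same grid.
#' @return HD95 in mm.
#' @export
hd95 <- function(a, b) {
  check_same_grid(a, b)
  if (sum(a$voxels) == 0L || sum(b$voxels) == 0L) empty_mask_error()
  pa <- voxel_coords(surface_voxels(a$voxels), a$spacing)
  pb <- voxel_coords(surface_voxels(b$voxels), b$spacing)
  d_ab <- stats::quantile(nearest_distances(pa, pb), 0.95, type = 7)
  d_ba <- stats::quantile(nearest_distances(pb, pa), 0.95, type = 7)
  unname(max(d_ab, d_ba))
}

#' Sanity-set label for a candidate mask
#'
#' A candidate is sanity-positive (expected to fail QC) when its Dice
#' against the ground truth falls below `dice_thresh` or its HD95
#' exceeds `hd_thresh`; both inequalities are strict, so a mask exactly
#' at the thresholds is negative.
#'
#' @param dice Dice coefficient vs. ground truth.
#' @param hd95 HD95 in mm vs. ground truth.
#' @param dice_thresh Dice threshold (default 0.95).
#' @param hd_thresh HD95 threshold in mm (default 15).
#' @return Logical: `TRUE` when the mask is expected to fail QC.
#' @export
sanity_label <- function(dice, hd95, dice_thresh = 0.95, hd_thresh = 15) {
  dice < dice_thresh | hd95 > hd_thresh
}

outcome_label <- function(sanity_positive, verdict) {
  ifelse(sanity_positive,
         ifelse(verdict == "fail", "TP", "FN"),
         ifelse(verdict == "fail", "FP", "TN"))
}

#' Confusion-matrix summary of QC verdicts against sanity labels
#'
#' Positives are masks expected to fail QC (sanity-positive); a "fail"
#' verdict on a positive is a true positive. Ratios with a zero
#' denominator are reported as `NA`, never 0.
#'
#' @param records Data.frame with logical `sanity_positive` and character
#'   `verdict` (`"pass"`/`"fail"`) columns, e.g. from [evaluate_masks()].
#' @return List of class `confusion_summary`: counts `tp`, `fp`, `tn`,
#'   `fn` and rates `sensitivity`, `specificity`, `precision`,
#'   `accuracy`.
#' @export
confusion_summary <- function(records) {
  if (NROW(records) < 1L) {
    insufficient_data_error("confusion summary needs at least one record")
  }
  out <- outcome_label(records$sanity_positive, records$verdict)
  tp <- sum(out == "TP"); fp <- sum(out == "FP")
  tn <- sum(out == "TN"); fn <- sum(out == "FN")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 precision = ratio(tp, tp + fp),
                 accuracy = ratio(tp + tn, tp + fp + tn + fn)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(paste0("<confusion_summary> TP %d  FP %d  TN %d  FN %d\n",
                     "  sensitivity %.4f  specificity %.4f  ",
                     "precision %.4f  accuracy %.4f\n"),
              x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity,
              x$precision, x$accuracy))
  invisible(x)
}

#' Pass rates per group
#'
#' Fraction of masks with a "pass" verdict in each group, in the style
#' of a method-by-modality pass-rate table.
#'
#' @param scores Data.frame with a `verdict` column (from
#'   [score_masks()]) plus optional grouping columns.
#' @param group_cols Character vector of grouping column names; when
#'   empty a single overall rate is returned.
#' @return Data.frame with the group columns, `n`, and `pass_rate`.
#' @export
pass_rate_table <- function(scores, group_cols = character(0)) {
  if (NROW(scores) < 1L) {
    insufficient_data_error("pass-rate table needs at least one score")
  }
  ok <- scores$verdict == "pass" & !is.na(scores$verdict)
  if (length(group_cols) == 0) {
    return(data.frame(n = nrow(scores), pass_rate = mean(ok)))
  }
  groups <- scores[, group_cols, drop = FALSE]
  agg <- stats::aggregate(ok, by = groups, FUN = function(v) c(length(v),
                                                               mean(v)))
  out <- data.frame(agg[, group_cols, drop = FALSE],
                    n = agg$x[, 1], pass_rate = agg$x[, 2])
  out[do.call(order, unname(as.list(out[group_cols]))), , drop = FALSE]
}

#' Evaluate candidate masks against ground truths and QC verdicts
#'
#' For each (ground-truth, candidate) pair computes Dice and HD95, the
#' sanity label, and — when a fitted model is given — the QC verdict and
#' the confusion outcome.
#'
#' @param candidates,ground_truths Lists of [brain_mask] objects, paired
#'   by position.
#' @param model Optional [fit_baseline()] model; when supplied, each
#'   candidate is scored and the outcome (TP/FP/TN/FN) recorded.
#' @param dice_thresh,hd_thresh Sanity thresholds, see [sanity_label()].
#' @return Data.frame of evaluation records: `mask_id`, `dice`, `hd95`,
#'   `sanity_positive`, and with a model `r`, `verdict`, `outcome`.
#' @export
evaluate_masks <- function(candidates, ground_truths, model = NULL,
                           dice_thresh = 0.95, hd_thresh = 15) {
  if (length(candidates) != length(ground_truths)) {
    config_error("candidates and ground truths must pair up one-to-one")
  }
  rows <- lapply(seq_along(candidates), function(i) {
    cand <- candidates[[i]]
    gt <- ground_truths[[i]]
    d <- dice(cand, gt)
    h <- if (sum(cand$voxels) > 0L && sum(gt$voxels) > 0L) {
      hd95(cand, gt)
    } else {
      Inf
    }
    data.frame(mask_id = cand$id, dice = d, hd95 = h,
               sanity_positive = sanity_label(d, h, dice_thresh, hd_thresh))
  })
  rec <- do.call(rbind, rows)
  if (!is.null(model)) {
    sc <- score_masks(candidates, model)
    rec$r <- sc$r
    rec$verdict <- sc$verdict
    rec$outcome <- outcome_label(rec$sanity_positive, rec$verdict)
  }
  rec
}
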