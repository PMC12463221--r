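#' @title Losses, metrics and statistical comparison
#' @description Soft-Dice and cross-entropy losses, their compound,
#'   thresholding, pixel confusion counts, the five segmentation metrics
#'   and paired t-tests with Bonferroni correction.
#' @name objectives
NULL

#' Loss configuration
#'
#' @param lambda1 weight of the Dice term (default 0.5).
#' @param lambda2 weight of the cross-entropy term (default 0.5).
#' @param epsilon numerical-stability constant, used both in the Dice
#'   ratio and inside the BCE logarithms (default 1e-5).
#' @return an object of class `fg_loss_config`.
#' @export
loss_config <- function(lambda1 = 0.5, lambda2 = 0.5, epsilon = 1e-5) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, epsilon > 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, epsilon = epsilon),
            class = "fg_loss_config")
}

check_pair <- function(y, yhat) {
  if (!identical(dim(y) %||% length(y), dim(yhat) %||% length(yhat)))
    stop("mask and prediction shapes differ")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Soft Dice loss
#'
#' `1 - (2 * sum(y * yhat) + eps) / (sum(y) + sum(yhat) + eps)`, computed
#' on the soft probability map (no thresholding).
#'
#' @param y binary ground-truth mask (array of 0/1).
#' @param yhat probability map of the same shape, values in `[0, 1]`.
#' @param cfg a [loss_config()].
#' @return scalar loss in `[0, 1)` for any non-empty mask.
#' @export
dice_loss <- function(y, yhat, cfg = loss_config()) {
  check_pair(y, yhat)
  eps <- cfg$epsilon
  1 - (2 * sum(y * yhat) + eps) / (sum(y) + sum(yhat) + eps)
}

#' Binary cross-entropy loss
#'
#' Pixel-averaged `-[y log(yhat + eps) + (1 - y) log(1 - yhat + eps)]`.
#' The stabilising epsilon sits inside the logarithms, so a perfect
#' binary prediction scores slightly below zero (about `-eps`), a
#' documented consequence of this parameterisation.
#'
#' @inheritParams dice_loss
#' @return scalar loss.
#' @export
bce_loss <- function(y, yhat, cfg = loss_config()) {
  check_pair(y, yhat)
  eps <- cfg$epsilon
  -mean(y * log(yhat + eps) + (1 - y) * log(1 - yhat + eps))
}

#' Compound segmentation loss
#'
#' `lambda1 * dice_loss + lambda2 * bce_loss`; with the default equal
#' weights of 0.5 this is the arithmetic mean of the two terms.
#'
#' @inheritParams dice_loss
#' @return scalar loss.
#' @export
compound_loss <- function(y, yhat, cfg = loss_config()) {
  cfg$lambda1 * dice_loss(y, yhat, cfg) + cfg$lambda2 * bce_loss(y, yhat, cfg)
}

# internal: batched loss + gradient wrt yhat.
# y, yhat: [H,W,B,1]; Dice is computed per image and averaged (each image
# is one Dice term, as in per-image evaluation); BCE is averaged over all
# pixels of the batch.
batch_loss_grad <- function(y, yhat, cfg = loss_config()) {
  d <- dim(y)
  hw <- d[1] * d[2]; B <- d[3]
  eps <- cfg$epsilon
  ym <- y; dim(ym) <- c(hw, B)
  pm <- yhat; dim(pm) <- c(hw, B)
  s <- colSums(ym * pm)
  u <- colSums(ym) + colSums(pm)
  dice_i <- 1 - (2 * s + eps) / (u + eps)
  l_dice <- mean(dice_i)
  # d dice_i / d p = -(2 y (u+eps) - (2 s+eps)) / (u+eps)^2
  gd <- -(sweep(2 * ym, 2L, u + eps, `*`) -
            matrix(2 * s + eps, hw, B, byrow = TRUE)) /
    matrix((u + eps)^2, hw, B, byrow = TRUE)
  gd <- gd / B
  n <- hw * B
  l_bce <- -mean(ym * log(pm + eps) + (1 - ym) * log(1 - pm + eps))
  gb <- -(ym / (pm + eps) - (1 - ym) / (1 - pm + eps)) / n
  g <- cfg$lambda1 * gd + cfg$lambda2 * gb
  dim(g) <- d
  list(loss = cfg$lambda1 * l_dice + cfg$lambda2 * l_bce,
       dice = l_dice, bce = l_bce, grad = g)
}

#' Threshold a probability map
#'
#' Values greater than or equal to the threshold map to foreground (1);
#' ties at the threshold are foreground by convention, which makes the
#' operation total and idempotent on binary input.
#'
#' @param yhat probability map.
#' @param threshold scalar in `[0, 1]` (default 0.5).
#' @return binary mask of the same shape.
#' @export
binarize <- function(yhat, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  out <- (yhat >= threshold) * 1
  out
}

#' Pixel-level confusion counts
#'
#' @param y binary ground-truth mask.
#' @param pred binary predicted mask of the same shape.
#' @return list with integer fields `tp`, `fp`, `tn`, `fn` summing to the
#'   pixel count.
#' @export
confusion_counts <- function(y, pred) {
  check_pair(y, pred)
  y <- y != 0; p <- pred != 0
  tp <- sum(y & p); fp <- sum(!y & p); fn <- sum(y & !p); tn <- sum(!y & !p)
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' The five segmentation metrics from confusion counts
#'
#' Dice `2TP/(2TP+FP+FN)`, IoU `TP/(TP+FP+FN)`, precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)` and pixel accuracy. Degenerate cases: if both
#' masks are empty (`TP+FP+FN = 0`) all overlap metrics are defined as 1
#' (a correctly empty prediction); if only a single denominator is zero
#' the corresponding metric is 0.
#'
#' @param counts output of [confusion_counts()].
#' @return list with `dice`, `iou`, `precision`, `recall`, `accuracy`,
#'   each in `[0, 1]`.
#' @export
segmentation_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  if (tp + fp + fn == 0) {
    dice <- 1; iou <- 1; precision <- 1; recall <- 1
  } else {
    dice <- 2 * tp / (2 * tp + fp + fn)
    iou <- tp / (tp + fp + fn)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  }
  accuracy <- (tp + tn) / (tp + fp + tn + fn)
  list(dice = dice, iou = iou, precision = precision, recall = recall,
       accuracy = accuracy)
}

#' Paired comparison of two score vectors
#'
#' Two-sided paired t-test with Bonferroni adjustment
#' `p_adj = min(1, n_comparisons * p)`. When every paired difference is
#' exactly zero the adjusted p-value is defined as 1 (no evidence of a
#' difference); a degenerate non-zero constant difference is surfaced as
#' an error rather than silently reported.
#'
#' @param scores_a,scores_b equal-length numeric vectors (length >= 2) of
#'   per-image scores for two methods.
#' @param n_comparisons number of simultaneous comparisons in the family.
#' @param alpha significance level (default 0.05).
#' @return list with `t`, `df`, `p_raw`, `p_adjusted`, `significant`,
#'   `mean_difference`.
#' @export
paired_comparison <- function(scores_a, scores_b, n_comparisons = 1L,
                              alpha = 0.05) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2L)
  diffs <- scores_a - scores_b
  if (stats::sd(diffs) == 0) {
    if (all(diffs == 0)) {
      return(list(t = 0, df = length(diffs) - 1L, p_raw = 1, p_adjusted = 1,
                  significant = FALSE, mean_difference = 0))
    }
    stop("paired differences have zero variance but non-zero mean; ",
         "the t statistic is undefined")
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  p_adj <- min(1, n_comparisons * tt$p.value)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_raw = tt$p.value, p_adjusted = p_adj,
       significant = p_adj < alpha,
       mean_difference = mean(diffs))
}

#' Write per-image metric reports
#'
#' @param per_image data frame of per-image metrics (one row per image).
#' @param summary named list of summary values.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return invisibly, the summary list.
#' @export
write_metric_report <- function(per_image, summary, csv_path = NULL,
                                json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(per_image, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
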