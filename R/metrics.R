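#' Voxelwise confusion counts between a predicted and a reference mask
#'
#' With X the predicted foreground set and Y the reference (ground-truth)
#' set: `tp = |X intersect Y|`, `fp = |X \\ Y|`, `fn = |Y \\ X|`, and `tn`
#' the remaining voxels.
#'
#' @param pred,gt [label_volume()]s of identical shape.
#' @return An object of class `confusion_counts` with integer fields
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(pred, gt) {
  stopifnot(inherits(pred, "label_volume"), inherits(gt, "label_volume"))
  if (!all(dim(pred$data) == dim(gt$data)))
    stop("confusion: mask shapes differ")
  p <- pred$data > 0; g <- gt$data > 0
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g)
  structure(list(tp = tp, fp = fp, fn = fn,
                 tn = length(p) - tp - fp - fn),
            class = "confusion_counts")
}

#' Overlap metrics from confusion counts
#'
#' Dice `2|XnY|/(|X|+|Y|)`, Jaccard `|XnY|/|XuY|`, accuracy, precision
#' `|XnY|/|X|`, recall `|XnY|/|Y|` and specificity. Any 0/0 ratio is defined
#' as 1 when both masks are empty (perfect agreement on emptiness) and 0
#' otherwise; such cases are flagged in the `"degenerate"` attribute.
#'
#' @param c a [confusion()] result.
#' @return Named list with `dice`, `jaccard`, `accuracy`, `precision`,
#'   `recall`, `specificity`.
#' @export
overlap_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  both_empty <- (c$tp + c$fp + c$fn) == 0
  degen <- character(0)
  ratio <- function(num, den, name) {
    if (den > 0) return(num / den)
    degen <<- c(degen, name)
    if (both_empty) 1.0 else 0.0
  }
  out <- list(
    dice = ratio(2 * c$tp, 2 * c$tp + c$fp + c$fn, "dice"),
    jaccard = ratio(c$tp, c$tp + c$fp + c$fn, "jaccard"),
    accuracy = (c$tp + c$tn) / (c$tp + c$fp + c$fn + c$tn),
    precision = ratio(c$tp, c$tp + c$fp, "precision"),
    recall = ratio(c$tp, c$tp + c$fn, "recall"),
    specificity = ratio(c$tn, c$tn + c$fp, "specificity"))
  attr(out, "degenerate") <- degen
  out
}

#' Voxelwise ROC AUC of a probability map against a binary reference
#'
#' Computed by the rank (Mann-Whitney) identity: the probability that a
#' randomly chosen foreground voxel receives a higher score than a randomly
#' chosen background voxel, with ties counting one half.
#'
#' @param prob a [volume()] of scores (probabilities).
#' @param gt a [label_volume()] containing both classes.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(prob, gt) {
  stopifnot(inherits(prob, "volume"), inherits(gt, "label_volume"))
  if (!all(dim(prob$data) == dim(gt$data)))
    stop("roc_auc: shapes differ")
  g <- gt$data > 0
  n1 <- sum(g); n0 <- sum(!g)
  if (n1 == 0 || n0 == 0)
    stop("roc_auc: undefined, ground truth contains a single class")
  r <- rank(as.vector(prob$data))
  (sum(r[g]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Symmetric 3D Hausdorff distance between two masks, in mm
#'
#' The maximum over both directed distances
#' `sup_x inf_y d(x, y)` between the foreground voxel centre sets, with
#' coordinates scaled by the voxel spacing (anisotropy honoured). Computed
#' with an exact Euclidean distance transform.
#'
#' @param pred,gt non-empty [label_volume()]s of identical shape.
#' @param spacing voxel spacing in mm (defaults to the prediction's).
#' @return Hausdorff distance in mm.
#' @export
hausdorff_3d <- function(pred, gt, spacing = pred$spacing) {
  stopifnot(inherits(pred, "label_volume"), inherits(gt, "label_volume"))
  if (!all(dim(pred$data) == dim(gt$data)))
    stop("hausdorff_3d: mask shapes differ")
  if (sum(pred$data) == 0 || sum(gt$data) == 0)
    stop("hausdorff_3d: undefined for an empty mask")
  d2gt <- edt_sq_3d(as.integer(gt$data), dim(gt$data), spacing)
  d2pr <- edt_sq_3d(as.integer(pred$data), dim(pred$data), spacing)
  sqrt(max(max(d2gt[pred$data > 0]), max(d2pr[gt$data > 0])))
}

#' Per-volume report of all eight evaluation metrics
#'
#' @param pred predicted [label_volume()].
#' @param gt ground-truth [label_volume()].
#' @param prob optional probability [volume()] for the AUC; without it the
#'   AUC is `NA`.
#' @param spacing mm spacing used for the Hausdorff distance.
#' @return One-row `data.frame` with columns `dice`, `jaccard`, `accuracy`,
#'   `precision`, `recall`, `specificity`, `auc`, `hausdorff_mm`. Undefined
#'   metrics (empty mask, single-class reference) are `NA`.
#' @export
evaluate_pair <- function(pred, gt, prob = NULL, spacing = gt$spacing) {
  om <- overlap_metrics(confusion(pred, gt))
  auc <- if (is.null(prob)) NA_real_ else
    tryCatch(roc_auc(prob, gt), error = function(e) NA_real_)
  hd <- tryCatch(hausdorff_3d(pred, gt, spacing), error = function(e) NA_real_)
  data.frame(dice = om$dice, jaccard = om$jaccard, accuracy = om$accuracy,
             precision = om$precision, recall = om$recall,
             specificity = om$specificity, auc = auc, hausdorff_mm = hd)
}

#' Exact two-sided paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped; ranks of tied absolute differences are
#' averaged. For n <= `exact_max` pairs the p-value comes from the exact
#' null distribution of the signed-rank statistic (computed by dynamic
#' programming over all sign assignments, valid under ties); above that a
#' normal approximation with tie correction is used.
#'
#' @param a,b equal-length numeric vectors of paired per-volume metric
#'   values; at least 5 non-zero differences are required.
#' @param exact_max largest n for which the exact distribution is used.
#' @return Two-sided p-value.
#' @export
wilcoxon_paired <- function(a, b, exact_max = 25L) {
  if (length(a) != length(b)) stop("wilcoxon_paired: unequal lengths")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("wilcoxon_paired: degenerate, all differences are zero")
  if (n < 5) stop("wilcoxon_paired: fewer than 5 non-zero differences")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of 2W over all 2^n sign assignments (doubled ranks are integers)
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    f <- numeric(tot + 1); f[1] <- 1
    for (ri in r2) {
      g <- f
      g[(ri + 1):(tot + 1)] <- g[(ri + 1):(tot + 1)] + f[1:(tot + 1 - ri)]
      f <- g
    }
    f <- f / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(f[1:(w2 + 1)])
    p_ge <- sum(f[(w2 + 1):(tot + 1)])
    min(1, 2 * min(p_le, p_ge))
  } else {
    ties <- table(r)
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sig2)
    min(1, 2 * pnorm(-abs(z)))
  }
}

#' Summarise per-volume metric rows as mean and standard deviation
#'
#' @param df data.frame of per-volume metric rows (as from [evaluate_pair()]).
#' @return data.frame with one `mean` and one `sd` row per metric column.
#' @export
summarise_metrics <- function(df) {
  num <- df[vapply(df, is.numeric, TRUE)]
  data.frame(metric = names(num),
             mean = vapply(num, function(v) mean(v, na.rm = TRUE), 0),
             sd = vapply(num, function(v) stats::sd(v, na.rm = TRUE), 0),
             n_missing = vapply(num, function(v) sum(is.na(v)), 0L),
             row.names = NULL)
}
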