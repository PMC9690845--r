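# Area and boundary metrics for BUS tumor segmentation, plus the Dice
# training loss.  The false positive rate follows the BUS convention:
# false-positive pixels divided by the number of ground-truth tumor pixels
# (NOT by the negatives), so it can exceed 1 when the spurious region is
# larger than the tumor.

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")))
}

as_binary <- function(mask) {
  m <- mask > 0
  storage.mode(m) <- "double"
  m
}

#' Dice loss
#'
#' `1 - (2 * sum(pred*target) + eps) / (sum(pred) + sum(target) + eps)`.
#' The smoothing term `eps` keeps the loss defined (and its gradient
#' bounded) for empty predictions and targets; it is the classic
#' soft-Dice objective used for training.
#'
#' @param pred numeric probability grid in `[0,1]`.
#' @param target binary grid of the same shape.
#' @param eps smoothing constant (default 1, one pixel's worth).
#' @return Scalar loss in `[0, 1)`.
#' @export
dice_loss <- function(pred, target, eps = 1.0) {
  check_same_shape(pred, target)
  if (any(pred < 0 | pred > 1)) stop("pred values outside [0,1]")
  s <- sum(pred * target)
  1 - (2 * s + eps) / (sum(pred) + sum(target) + eps)
}

# Gradient of dice_loss with respect to pred (used by the trainer).
dice_loss_grad <- function(pred, target, eps = 1.0) {
  s <- sum(pred * target)
  den <- sum(pred) + sum(target) + eps
  -(2 * target * den - (2 * s + eps)) / den^2
}

#' Area-overlap metrics with the BUS false-positive-rate convention
#'
#' With `TP`, `FP`, `FN` the pixel confusion counts against a nonempty
#' ground truth of size `|gt|`:
#' `tpr = TP/|gt|`, `fpr = FP/|gt|` (denominator is the *actual positives*,
#' so `fpr > 1` whenever `FP > |gt|`), `ji = TP/(TP+FP+FN)`,
#' `dsc = 2TP/(2TP+FP+FN)`, `aer = (FP+FN)/|gt| = fpr + (1 - tpr)`.
#'
#' @param pred_mask,gt_mask binary grids of equal shape; `gt_mask` must be
#'   nonempty.
#' @return Named list `tpr, fpr, ji, dsc, aer`.
#' @export
area_metrics <- function(pred_mask, gt_mask) {
  check_same_shape(pred_mask, gt_mask)
  p <- pred_mask > 0; g <- gt_mask > 0
  npos <- sum(g)
  if (npos == 0) stop("empty ground-truth mask: area metrics undefined")
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g)
  ji <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  list(tpr = tp / npos,
       fpr = fp / npos,
       ji = ji,
       dsc = 2 * tp / (2 * tp + fp + fn),
       aer = (fp + fn) / npos)
}

#' Boundary pixels of a binary mask
#'
#' Foreground pixels with at least one 4-neighbour outside the foreground;
#' the image border counts as outside.
#'
#' @param mask nonempty binary grid.
#' @return Integer matrix with columns `row`, `col` (one boundary pixel
#'   per row).
#' @export
boundary_pixels <- function(mask) {
  m <- mask > 0
  if (!any(m)) stop("empty mask has no boundary")
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  inner <- pad[2:(H + 1L), 2:(W + 1L)]
  up    <- pad[1:H, 2:(W + 1L)]
  down  <- pad[3:(H + 2L), 2:(W + 1L)]
  left  <- pad[2:(H + 1L), 1:W]
  right <- pad[2:(H + 1L), 3:(W + 2L)]
  b <- inner & !(up & down & left & right)
  which(b, arr.ind = TRUE, useNames = FALSE)
}

#' Hausdorff and mean boundary distances between two masks
#'
#' With `A`, `G` the boundary pixel sets and `d(p, S)` the Euclidean
#' distance from a pixel to the nearest member of `S`:
#' `hd = max(max_a d(a,G), max_g d(g,A))` (the exact, maximum Hausdorff
#' distance) and `mae = (sum_a d(a,G) + sum_g d(g,A)) / (|A| + |G|)`
#' (the average symmetric surface distance).  Both are symmetric in their
#' arguments and `hd >= mae` always.
#'
#' @param pred_mask,gt_mask nonempty binary grids of equal shape.
#' @return Named list `hd`, `mae` (pixels).
#' @export
boundary_distances <- function(pred_mask, gt_mask) {
  check_same_shape(pred_mask, gt_mask)
  A <- boundary_pixels(pred_mask)
  G <- boundary_pixels(gt_mask)
  D <- sqrt(outer(A[, 1L], G[, 1L], "-")^2 + outer(A[, 2L], G[, 2L], "-")^2)
  d_ag <- apply(D, 1L, min)
  d_ga <- apply(D, 2L, min)
  list(hd = max(max(d_ag), max(d_ga)),
       mae = (sum(d_ag) + sum(d_ga)) / (length(d_ag) + length(d_ga)))
}

#' Evaluate one predicted probability map against a ground-truth mask
#'
#' Binarizes the probability map at `threshold` and computes all seven
#' metrics.  An empty prediction gets the natural area metrics
#' (`tpr = fpr = 0`, `aer = 1`) but undefined boundary distances, which
#' are returned as `NA` with `flag = "empty_pred"` so that averaging code
#' can report the exclusion.
#'
#' @param prob_map numeric probability grid.
#' @param gt_mask nonempty binary grid of the same shape.
#' @param threshold binarization threshold (default 0.5).
#' @param id sample identifier carried into the report row.
#' @param group size-group label carried into the report row (optional).
#' @return One-row data.frame: `id, group, tpr, fpr, ji, dsc, aer, hd,
#'   mae, flag`.
#' @export
evaluate_sample <- function(prob_map, gt_mask, threshold = 0.5,
                            id = NA_character_, group = NA_character_) {
  check_same_shape(prob_map, gt_mask)
  if (!any(gt_mask > 0)) stop("empty ground-truth mask: sample not evaluable")
  pred <- prob_map > threshold
  am <- area_metrics(pred, gt_mask)
  if (any(pred)) {
    bd <- boundary_distances(pred, gt_mask)
    flag <- ""
  } else {
    bd <- list(hd = NA_real_, mae = NA_real_)
    flag <- "empty_pred"
  }
  data.frame(id = id, group = group,
             tpr = am$tpr, fpr = am$fpr, ji = am$ji, dsc = am$dsc,
             aer = am$aer, hd = bd$hd, mae = bd$mae, flag = flag,
             stringsAsFactors = FALSE)
}
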