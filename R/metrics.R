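#' Dice score coefficient
#'
#' Spatial overlap between a predicted binary mask P and ground truth G:
#' \deqn{DSC = 2|P \cap G| / (|P| + |G|)}
#' Two empty masks score 1 (perfect agreement by convention).
#'
#' @param P,G logical matrices of equal shape (numeric/integer inputs are
#'   treated as foreground where nonzero).
#' @return fraction in \[0, 1\].
#' @export
dice_score <- function(P, G) {
  pg <- check_mask_pair(P, G)
  i <- sum(pg$P & pg$G)
  s <- sum(pg$P) + sum(pg$G)
  if (s == 0L) return(1)
  2 * i / s
}

#' Intersection over union (Jaccard index)
#'
#' \deqn{IoU = |P \cap G| / |P \cup G|}
#' Two empty masks score 1 by convention. Related to the Dice score by
#' `dice = 2 * iou / (1 + iou)`.
#'
#' @inheritParams dice_score
#' @return fraction in \[0, 1\].
#' @export
iou_score <- function(P, G) {
  pg <- check_mask_pair(P, G)
  u <- sum(pg$P | pg$G)
  if (u == 0L) return(1)
  sum(pg$P & pg$G) / u
}

check_mask_pair <- function(P, G) {
  if (!is.matrix(P) || !is.matrix(G) || !all(dim(P) == dim(G)))
    stop("shape mismatch between prediction and ground truth")
  list(P = P != 0, G = G != 0)
}

#' Evaluate a multi-class label against ground truth
#'
#' Per-class IoU by one-vs-rest binarisation, mean IoU over the requested
#' class set (background excluded by default, matching per-structure
#' reporting), and two Dice aggregations: `dice`, computed on the
#' foreground union (any nonzero class), and `dice_macro`, the mean of
#' per-class Dice over the class set.
#'
#' @param pred,truth integer label matrices (values in \{0, 1, 2\}) of
#'   equal shape.
#' @param classes classes entering mIoU / macro Dice; subset of 0:2.
#' @return object of class `metrics_report`: list with `dice`,
#'   `dice_macro`, `iou_per_class` (named over 0:2), `miou` and
#'   `pixel_counts`.
#' @export
evaluate_label <- function(pred, truth, classes = c(1L, 2L)) {
  if (!is.matrix(pred) || !is.matrix(truth) || !all(dim(pred) == dim(truth)))
    stop("shape mismatch between prediction and ground truth")
  if (!all(classes %in% 0:2)) stop("unknown class id in `classes`")
  all_classes <- 0:2
  iou <- vapply(all_classes, function(k) iou_score(pred == k, truth == k), numeric(1))
  dice_k <- vapply(all_classes, function(k) dice_score(pred == k, truth == k), numeric(1))
  names(iou) <- names(dice_k) <- c("background", "osteocyte", "dendrite")
  counts <- rbind(pred = vapply(all_classes, function(k) sum(pred == k), numeric(1)),
                  truth = vapply(all_classes, function(k) sum(truth == k), numeric(1)))
  colnames(counts) <- names(iou)
  out <- list(
    dice = dice_score(pred > 0L, truth > 0L),
    dice_macro = mean(dice_k[classes + 1L]),
    iou_per_class = iou,
    miou = mean(iou[classes + 1L]),
    pixel_counts = counts)
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("DSC %.3f | mIoU %.3f | osteocyte IoU %.3f | dendrite IoU %.3f\n",
              x$dice, x$miou, x$iou_per_class[["osteocyte"]],
              x$iou_per_class[["dendrite"]]))
  invisible(x)
}
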