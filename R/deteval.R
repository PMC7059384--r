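#' Intersection over union of two pixel boxes
#'
#' Boxes are axis-aligned in corner form `(xmin, ymin, xmax, ymax)`
#' with `xmin < xmax`, `ymin < ymax` (half-open pixel coordinates).
#' Disjoint boxes score 0, identical boxes 1.
#'
#' @param a,b Numeric vectors `c(xmin, ymin, xmax, ymax)` or `n x 4`
#'   matrices (recycled row-wise).
#' @return IoU values in `[0, 1]`.
#' @export
#' @examples
#' box_iou(c(0, 0, 2, 2), c(1, 0, 3, 2))  # 1/3
box_iou <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 4)
  b <- matrix(as.numeric(b), ncol = 4)
  if (any(a[, 3] <= a[, 1]) || any(a[, 4] <= a[, 2]) ||
      any(b[, 3] <= b[, 1]) || any(b[, 4] <= b[, 2]))
    stop("malformed box: require xmin < xmax and ymin < ymax",
         call. = FALSE)
  n <- max(nrow(a), nrow(b))
  a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (area_a + area_b - inter)
}

#' Greedily match detections to ground truth
#'
#' Detections are processed in order of descending confidence (ties kept
#' in input order); each is matched to the not-yet-matched ground-truth
#' box of the same class and image with the highest IoU, and flagged a
#' true positive when that IoU reaches the threshold (`>=` by default,
#' strictly `>` with `strict = TRUE`). Each ground truth can be matched
#' at most once; all other detections are false positives.
#'
#' @param detections Data frame with columns `image_id`, `class_id`,
#'   `xmin`, `ymin`, `xmax`, `ymax`, `confidence`.
#' @param ground_truth Data frame with columns `image_id`, `class_id`,
#'   `xmin`, `ymin`, `xmax`, `ymax`.
#' @param iou_threshold Matching threshold (default 0.5).
#' @param strict If `TRUE`, require IoU strictly above the threshold.
#' @return `detections` reordered by descending confidence with added
#'   logical column `tp` and numeric column `match_iou`.
#' @export
match_detections <- function(detections, ground_truth,
                             iou_threshold = 0.5, strict = FALSE) {
  need_d <- c("image_id", "class_id", "xmin", "ymin", "xmax", "ymax",
              "confidence")
  stopifnot(all(need_d %in% names(detections)),
            all(setdiff(need_d, "confidence") %in% names(ground_truth)))
  ord <- order(-detections$confidence)   # stable: ties keep input order
  d <- detections[ord, , drop = FALSE]
  d$tp <- logical(nrow(d))
  d$match_iou <- NA_real_
  used <- logical(nrow(ground_truth))
  for (i in seq_len(nrow(d))) {
    cand <- which(!used &
                  ground_truth$image_id == d$image_id[i] &
                  ground_truth$class_id == d$class_id[i])
    if (length(cand) == 0L) next
    ious <- box_iou(as.numeric(d[i, c("xmin", "ymin", "xmax", "ymax")]),
                    as.matrix(ground_truth[cand, c("xmin", "ymin",
                                                   "xmax", "ymax")]))
    best <- which.max(ious)
    hit <- if (strict) ious[best] > iou_threshold
           else ious[best] >= iou_threshold
    if (hit) {
      d$tp[i] <- TRUE
      d$match_iou[i] <- ious[best]
      used[cand[best]] <- TRUE
    }
  }
  rownames(d) <- NULL
  d
}

#' Precision-recall curve from ordered match flags
#'
#' Cumulative precision and recall down the confidence ordering:
#' `precision_k = TP_k / k`, `recall_k = TP_k / n_gt`.
#'
#' @param tp_flags Logical vector of per-detection true-positive flags,
#'   already ordered by descending confidence.
#' @param n_gt Number of ground-truth boxes (>= 1).
#' @return Data frame with columns `precision`, `recall`.
#' @export
pr_curve <- function(tp_flags, n_gt) {
  if (n_gt < 1) stop("n_gt must be at least 1", call. = FALSE)
  tp_flags <- as.logical(tp_flags)
  k <- seq_along(tp_flags)
  ctp <- cumsum(tp_flags)
  data.frame(precision = if (length(k)) ctp / k else numeric(0),
             recall = if (length(k)) ctp / n_gt else numeric(0))
}

#' Average precision at a fixed IoU threshold
#'
#' Pools all detections of one class across images, matches them with
#' [match_detections()], and accumulates the area under the
#' precision-recall curve by left Riemann summation over the recall
#' steps: `AP = sum_k P(k) * (recall_k - recall_{k-1})`. No
#' interpolation or fixed-point sampling is applied.
#'
#' @inheritParams match_detections
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(detections, ground_truth,
                              iou_threshold = 0.5, strict = FALSE) {
  if (nrow(ground_truth) == 0L)
    stop("average precision undefined without ground truth", call. = FALSE)
  if (nrow(detections) == 0L) return(0)
  d <- match_detections(detections, ground_truth, iou_threshold, strict)
  pr <- pr_curve(d$tp, nrow(ground_truth))
  drec <- diff(c(0, pr$recall))
  sum(pr$precision * drec)
}

#' Mean average precision over classes
#'
#' @param per_class_aps Numeric vector of per-class AP values.
#' @return Their arithmetic mean.
#' @export
mean_ap <- function(per_class_aps) {
  if (length(per_class_aps) < 1L)
    stop("need at least one class AP", call. = FALSE)
  mean(per_class_aps)
}

#' Evaluate detections against ground truth
#'
#' Per-class average precision at the given IoU threshold plus the mAP,
#' the standard single-number summary for a two-class weed/crop
#' detector.
#'
#' @inheritParams match_detections
#' @return A list with `per_class` (data frame `class_id`, `ap`,
#'   `n_gt`, `n_det`) and `map`.
#' @export
evaluate_detections <- function(detections, ground_truth,
                                iou_threshold = 0.5, strict = FALSE) {
  if (nrow(ground_truth) == 0L)
    stop("no ground truth to evaluate against", call. = FALSE)
  classes <- sort(unique(ground_truth$class_id))
  aps <- vapply(classes, function(cl) {
    average_precision(detections[detections$class_id == cl, , drop = FALSE],
                      ground_truth[ground_truth$class_id == cl, , drop = FALSE],
                      iou_threshold, strict)
  }, numeric(1))
  per_class <- data.frame(
    class_id = classes, ap = aps,
    n_gt = vapply(classes, function(cl)
      sum(ground_truth$class_id == cl), numeric(1)),
    n_det = vapply(classes, function(cl)
      sum(detections$class_id == cl), numeric(1)))
  list(per_class = per_class, map = mean_ap(aps))
}
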