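#' Co-centred IoU of two box sizes
#'
#' Intersection over union of two axis-aligned boxes aligned at a common
#' centre, so only their widths and heights matter:
#' `min(w) * min(h) / (w1*h1 + w2*h2 - min(w) * min(h))`. This is the
#' similarity underlying the YOLO-style anchor clustering distance
#' `1 - IoU`, which is scale-invariant (unlike Euclidean distance on
#' pixel sizes).
#'
#' @param a,b Box sizes: numeric `c(w, h)` vectors or `n x 2` matrices
#'   (recycled against each other row-wise).
#' @return IoU values in `[0, 1]`.
#' @export
#' @examples
#' wh_iou(c(2, 2), c(4, 4))  # 0.25
wh_iou <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  if (any(a <= 0) || any(b <= 0))
    stop("box dimensions must be positive", call. = FALSE)
  n <- max(nrow(a), nrow(b))
  a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  inter <- pmin(a[, 1], b[, 1]) * pmin(a[, 2], b[, 2])
  inter / (a[, 1] * a[, 2] + b[, 1] * b[, 2] - inter)
}

# pairwise distance matrix between n x 2 points and k x 2 centroids
anchor_dist <- function(pts, centroids, distance) {
  n <- nrow(pts); k <- nrow(centroids)
  d <- matrix(0, n, k)
  for (j in seq_len(k)) {
    if (distance == "iou") {
      d[, j] <- 1 - wh_iou(pts, centroids[j, , drop = FALSE])
    } else {
      d[, j] <- (pts[, 1] - centroids[j, 1])^2 + (pts[, 2] - centroids[j, 2])^2
    }
  }
  d
}

# k-means++ style seeding: first centre uniform, later centres with
# probability proportional to distance to the nearest chosen centre
seed_centroids <- function(pts, k, distance) {
  n <- nrow(pts)
  chosen <- integer(k)
  chosen[1] <- sample.int(n, 1L)
  if (k > 1L) for (j in 2:k) {
    d <- anchor_dist(pts, pts[chosen[1:(j - 1)], , drop = FALSE], distance)
    dmin <- apply(d, 1, min)
    if (sum(dmin) <= 0) {
      chosen[j] <- sample.int(n, 1L)
    } else {
      chosen[j] <- sample.int(n, 1L, prob = dmin / sum(dmin))
    }
  }
  pts[chosen, , drop = FALSE]
}

lloyd_once <- function(pts, k, distance, max_iter) {
  # Lloyd iterations in partition space: each step reassigns points to
  # the nearest centroid and replaces centroids by cluster means, then
  # scores the partition with its own means. The mean update is optimal
  # for squared Euclidean distance but only a heuristic for 1 - IoU,
  # where it could occasionally raise the objective; such a step is
  # rejected and the best earlier state kept, so descent is monotone
  # and the reported centroids are always the means of their clusters.
  n <- nrow(pts)
  centroids <- seed_centroids(pts, k, distance)
  best <- NULL
  assign_prev <- rep(0L, n)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d <- anchor_dist(pts, centroids, distance)
    assign <- max.col(-d, ties.method = "first")
    new_cent <- centroids
    for (j in seq_len(k)) {
      members <- assign == j
      if (!any(members)) {
        # empty cluster: reseed from the point farthest from its centroid
        far <- which.max(d[cbind(seq_len(n), assign)])
        new_cent[j, ] <- pts[far, ]
        assign[far] <- j
      } else {
        new_cent[j, ] <- colMeans(pts[members, , drop = FALSE])
      }
    }
    dd <- anchor_dist(pts, new_cent, distance)
    obj <- sum(dd[cbind(seq_len(n), assign)])  # partition's own means
    if (!is.null(best) && obj > best$objective + 1e-12) break
    trace <- c(trace, obj)
    best <- list(centroids = new_cent, assignment = assign,
                 objective = obj)
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
    centroids <- new_cent
  }
  best$trace <- trace
  best
}

#' Estimate anchor-box sizes by k-means clustering
#'
#' Clusters training-set box sizes (w, h) with Lloyd's algorithm under
#' either the YOLO anchor distance `1 - wh_iou` (default) or squared
#' Euclidean distance; centroid update is the per-cluster mean. Runs
#' `nstart` seeded k-means++ initializations and keeps the solution with
#' the lowest total within-cluster distance. Anchors are returned sorted
#' ascending by area; for even `k` they are also split into a fine-scale
#' half (the `k/2` smallest, for the high-resolution detection grid) and
#' a coarse-scale half.
#'
#' @param dims Box sizes: an `n x 2` matrix or data frame of positive
#'   widths and heights (pixels).
#' @param k Number of anchors (clusters); `n >= k` required.
#' @param distance `"iou"` or `"euclidean"`.
#' @param seed Optional integer seed making the estimate reproducible.
#' @param max_iter Lloyd iteration cap per start.
#' @param nstart Number of independent initializations.
#' @return An object of class `"anchor_set"`: list with `anchors`
#'   (`k x 2` matrix, area-ascending), `fine` and `coarse` (for even
#'   `k`), `objective`, `assignment`, and attribute `objective_trace`
#'   (per-iteration objective of the winning start).
#' @export
kmeans_anchors <- function(dims, k, distance = c("iou", "euclidean"),
                           seed = NULL, max_iter = 100L, nstart = 5L) {
  distance <- match.arg(distance)
  pts <- as.matrix(dims)
  if (ncol(pts) != 2L) stop("dims must have two columns (w, h)", call. = FALSE)
  storage.mode(pts) <- "double"
  if (any(pts <= 0)) stop("box dimensions must be positive", call. = FALSE)
  if (nrow(pts) < k)
    stop(sprintf("need at least k = %d boxes, got %d", k, nrow(pts)),
         call. = FALSE)
  best <- with_local_seed(seed, {
    runs <- lapply(seq_len(nstart), function(i)
      lloyd_once(pts, k, distance, max_iter))
    runs[[which.min(vapply(runs, `[[`, numeric(1), "objective"))]]
  })
  ord <- order(best$centroids[, 1] * best$centroids[, 2])
  anchors <- best$centroids[ord, , drop = FALSE]
  colnames(anchors) <- c("w", "h")
  rownames(anchors) <- NULL
  res <- structure(list(
    anchors = anchors,
    fine = if (k %% 2L == 0L) anchors[seq_len(k / 2), , drop = FALSE],
    coarse = if (k %% 2L == 0L) anchors[(k / 2 + 1):k, , drop = FALSE],
    objective = best$objective,
    assignment = order(ord)[best$assignment],
    distance = distance, k = k
  ), class = "anchor_set")
  attr(res, "objective_trace") <- best$trace
  res
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("Anchor set: %d anchors (%s distance), objective %.4f\n",
              x$k, x$distance, x$objective))
  pairs <- apply(x$anchors, 1, function(a)
    sprintf("[%.0f,%.0f]", a[1], a[2]))
  cat(" ", paste(pairs, collapse = ", "), "\n")
  if (!is.null(x$fine))
    cat(sprintf("  fine scale: %s | coarse scale: %s\n",
                paste(pairs[seq_len(x$k / 2)], collapse = ", "),
                paste(pairs[(x$k / 2 + 1):x$k], collapse = ", ")))
  invisible(x)
}

#' Assign six anchors to the two detection scales
#'
#' Sorts six anchors ascending by area (stable, so equal-area anchors
#' keep their input order) and assigns the three smallest to the fine
#' (high-resolution) detection grid and the three largest to the coarse
#' grid, the standard convention for two-scale grid detectors.
#'
#' @param anchors A `6 x 2` matrix of (w, h) pairs, or an
#'   `"anchor_set"` with six anchors.
#' @return List with `fine` and `coarse`, each a `3 x 2` matrix.
#' @export
split_scales <- function(anchors) {
  if (inherits(anchors, "anchor_set")) anchors <- anchors$anchors
  anchors <- as.matrix(anchors)
  if (nrow(anchors) != 6L || ncol(anchors) != 2L)
    stop("split_scales expects exactly 6 anchors (w, h)", call. = FALSE)
  ord <- order(anchors[, 1] * anchors[, 2])  # stable for ties
  sorted <- anchors[ord, , drop = FALSE]
  colnames(sorted) <- c("w", "h")
  list(fine = sorted[1:3, , drop = FALSE],
       coarse = sorted[4:6, , drop = FALSE])
}

#' Format anchors in the darknet configuration dialect
#'
#' @param anchors Matrix of (w, h) pairs or an `"anchor_set"`.
#' @return A single string like `"14,20, 32,38, ..."`.
#' @export
format_anchors <- function(anchors) {
  if (inherits(anchors, "anchor_set")) anchors <- anchors$anchors
  anchors <- as.matrix(anchors)
  paste(apply(anchors, 1, function(a)
    sprintf("%g,%g", round(a[1]), round(a[2]))), collapse = ", ")
}
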