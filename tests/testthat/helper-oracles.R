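# Independent oracles and small fixture builders used across tests.
# Each oracle is a deliberately naive re-derivation (loops, brute force,
# dense integration) of the quantity the package computes analytically.

# between-class variance of a histogram split: bins 1..t vs t+1..nbins,
# computed by direct group statistics over bin levels
split_variance <- function(counts, t) {
  levels <- seq_along(counts) - 1
  n0 <- sum(counts[1:t]); n1 <- sum(counts) - n0
  if (n0 == 0 || n1 == 0) return(0)
  mu0 <- sum(counts[1:t] * levels[1:t]) / n0
  mu1 <- sum(counts[-(1:t)] * levels[-(1:t)]) / n1
  w0 <- n0 / sum(counts); w1 <- n1 / sum(counts)
  w0 * w1 * (mu0 - mu1)^2
}

# histogram of a sample under the package's 256-bin 8-bit convention
otsu_histogram <- function(v, nbins = 256L) {
  lo <- min(v); hi <- max(v)
  idx <- pmin(nbins - 1L, floor((v - lo) / (hi - lo) * (nbins - 1L)))
  tabulate(idx + 1L, nbins = nbins)
}

# brute-force best between-class variance over all bin splits
otsu_best_variance <- function(v, nbins = 256L) {
  counts <- otsu_histogram(v, nbins)
  max(vapply(1:(nbins - 1L), function(t) split_variance(counts, t),
             numeric(1)))
}

# variance attained by the partition a concrete threshold induces,
# scored on the binned levels like split_variance
otsu_attained_variance <- function(v, thr, nbins = 256L) {
  lo <- min(v); hi <- max(v)
  lev <- pmin(nbins - 1L, floor((v - lo) / (hi - lo) * (nbins - 1L)))
  left <- v <= thr
  if (!any(left) || all(left)) return(0)
  w0 <- mean(left); w1 <- 1 - w0
  w0 * w1 * (mean(lev[left]) - mean(lev[!left]))^2
}

# scalar-loop grid loss mirroring the three printed formulas
naive_grid_loss <- function(pred, target, alpha_coord = 5,
                            alpha_noobj = 0.5) {
  S <- target$S; B <- target$B; C <- target$n_classes
  tt <- target$tensor
  l1 <- 0; l2 <- 0; l3 <- 0
  for (r in 1:S) for (cc in 1:S) {
    for (j in 1:B) {
      if (target$obj[r, cc, j]) {
        l1 <- l1 + alpha_coord * ((tt[r, cc, j, 1] - pred[r, cc, j, 1])^2 +
                                  (tt[r, cc, j, 2] - pred[r, cc, j, 2])^2)
        l1 <- l1 + alpha_coord *
          ((sqrt(tt[r, cc, j, 3]) - sqrt(pred[r, cc, j, 3]))^2 +
           (sqrt(tt[r, cc, j, 4]) - sqrt(pred[r, cc, j, 4]))^2)
        l2 <- l2 + (tt[r, cc, j, 5] - pred[r, cc, j, 5])^2
      } else {
        l2 <- l2 + alpha_noobj * (tt[r, cc, j, 5] - pred[r, cc, j, 5])^2
      }
    }
    js <- which(target$obj[r, cc, ])
    if (length(js) > 0) {
      if (length(js) > 1) {
        areas <- tt[r, cc, js, 3] * tt[r, cc, js, 4]
        js <- js[which.max(areas)]
      }
      for (ch in 1:C)
        l3 <- l3 + (tt[r, cc, js, 5 + ch] - pred[r, cc, js, 5 + ch])^2
    }
  }
  list(coord = l1, conf = l2, class = l3, total = l1 + l2 + l3)
}

# dense numerical integration of the step precision-recall curve
ap_by_integration <- function(tp_flags, n_gt, grid_n = 20000L) {
  ctp <- cumsum(tp_flags)
  prec <- ctp / seq_along(tp_flags)
  rec <- ctp / n_gt
  u <- (seq_len(grid_n) - 0.5) / grid_n  # midpoints in (0, 1)
  p_at <- vapply(u, function(r) {
    k <- which(rec >= r)
    if (length(k) == 0L) 0 else prec[k[1]]
  }, numeric(1))
  mean(p_at)
}

# literal greedy matcher written as an explicit loop (no vectorization,
# no reordering tricks) for cross-checking match_detections
greedy_match_oracle <- function(dets, gts, thr = 0.5) {
  ord <- order(-dets$confidence)
  used <- rep(FALSE, nrow(gts))
  tp <- rep(FALSE, nrow(dets))
  for (i in ord) {
    best_iou <- -1; best_g <- NA
    for (g in seq_len(nrow(gts))) {
      if (used[g]) next
      if (gts$image_id[g] != dets$image_id[i]) next
      if (gts$class_id[g] != dets$class_id[i]) next
      iou <- box_iou(as.numeric(dets[i, c("xmin", "ymin", "xmax", "ymax")]),
                     as.numeric(gts[g, c("xmin", "ymin", "xmax", "ymax")]))
      if (iou > best_iou) { best_iou <- iou; best_g <- g }
    }
    if (!is.na(best_g) && best_iou >= thr) {
      tp[i] <- TRUE
      used[best_g] <- TRUE
    }
  }
  tp[ord]
}

# exhaustive k-means objective: minimum over every assignment of points
# to k clusters of the summed point-to-cluster-mean distance
exhaustive_kmeans_objective <- function(pts, k, distance) {
  n <- nrow(pts)
  point_dist <- function(p, centre) {
    if (distance == "iou") 1 - wh_iou(p, centre)
    else sum((p - centre)^2)
  }
  best <- Inf
  assign <- rep(1L, n)
  repeat {
    obj <- 0
    for (j in 1:k) {
      members <- which(assign == j)
      if (length(members) == 0) next
      centre <- colMeans(pts[members, , drop = FALSE])
      for (m in members)
        obj <- obj + point_dist(pts[m, ], centre)
    }
    if (obj < best) best <- obj
    # next assignment in base-k counting
    i <- 1L
    while (i <= n && assign[i] == k) { assign[i] <- 1L; i <- i + 1L }
    if (i > n) break
    assign[i] <- assign[i] + 1L
  }
  best
}

# a uniform-colour test image
flat_image <- function(h, w, rgb) {
  arr <- array(0L, dim = c(h, w, 3))
  for (ch in 1:3) arr[, , ch] <- as.integer(rgb[ch])
  arr
}

# single-plant sources derived from procedural scenes, for compositing
make_sources <- function(n, class_id, hw = c(96L, 96L), seed0 = 100L) {
  lapply(seq_len(n), function(i) {
    scene <- generate_field_fixture(seed0 + i, hw,
                                    n_beet = if (class_id == 0L) 1L else 0L,
                                    n_weed = if (class_id == 0L) 0L else 1L)
    plant_source(scene$image, scene$masks[[1]], class_id,
                 id = sprintf("c%d_%d", class_id, i))
  })
}
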