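#' Loss weighting constants
#'
#' Weighting of the grid detection loss: the coordinate term is
#' up-weighted (`alpha_coord = 5`) and the no-object confidence term
#' down-weighted (`alpha_noobj = 0.5`), a 10:1 ratio that focuses
#' training on localization over the abundant empty cells.
#'
#' @param alpha_coord Coordinate-loss weight.
#' @param alpha_noobj Background-confidence weight.
#' @return A named list.
#' @export
loss_weights <- function(alpha_coord = 5, alpha_noobj = 0.5) {
  stopifnot(alpha_coord > 0, alpha_noobj >= 0)
  list(alpha_coord = alpha_coord, alpha_noobj = alpha_noobj)
}

#' Encode ground-truth boxes onto a detection grid
#'
#' Builds the `S x S x B x (5 + C)` target tensor and the responsibility
#' indicator for one detection scale. Each normalized box is assigned to
#' the grid cell containing its centre (half-open cells: a centre
#' exactly on a boundary belongs to the higher-index cell) and to the
#' anchor slot with the highest co-centred IoU against the box's
#' (w, h). The responsible slot carries the centre offset within the
#' cell (`x`, `y` in `[0, 1)`), the normalized width and height, a
#' confidence target of 1, and a one-hot class vector; every other slot
#' has confidence target 0. If two boxes claim the same (cell, anchor)
#' slot the larger-area box is kept, with a warning.
#'
#' @param labels Data frame with columns `class_id`, `cx`, `cy`, `w`,
#'   `h` (darknet-normalized).
#' @param S Grid side length.
#' @param anchors `B x 2` matrix of anchor (w, h) in normalized image
#'   units.
#' @param n_classes Number of classes `C`.
#' @return A list of class `"grid_target"`: `tensor`
#'   (`S x S x B x (5 + C)`, indexed row, column, anchor, channel with
#'   channels x, y, w, h, conf, classes) and `obj` (`S x S x B` logical
#'   responsibility indicator).
#' @export
encode_targets <- function(labels, S, anchors, n_classes) {
  S <- as.integer(S); stopifnot(S >= 1)
  anchors <- matrix(as.numeric(as.matrix(anchors)), ncol = 2)
  B <- nrow(anchors)
  n_classes <- as.integer(n_classes); stopifnot(n_classes >= 1)
  tensor <- array(0, dim = c(S, S, B, 5L + n_classes))
  obj <- array(FALSE, dim = c(S, S, B))
  if (nrow(labels) == 0L)
    return(structure(list(tensor = tensor, obj = obj, S = S, B = B,
                          n_classes = n_classes), class = "grid_target"))
  stopifnot(all(c("class_id", "cx", "cy", "w", "h") %in% names(labels)),
            all(labels$w > 0), all(labels$h > 0),
            all(labels$cx >= 0), all(labels$cx <= 1),
            all(labels$cy >= 0), all(labels$cy <= 1),
            all(labels$class_id >= 0), all(labels$class_id < n_classes))
  for (i in seq_len(nrow(labels))) {
    cx <- labels$cx[i]; cy <- labels$cy[i]
    col <- min(S - 1L, floor(cx * S))   # 0-based cell coordinates
    row <- min(S - 1L, floor(cy * S))
    j <- which.max(wh_iou(matrix(c(labels$w[i], labels$h[i]), ncol = 2),
                          anchors))
    if (obj[row + 1L, col + 1L, j]) {
      old_area <- tensor[row + 1L, col + 1L, j, 3] *
                  tensor[row + 1L, col + 1L, j, 4]
      new_area <- labels$w[i] * labels$h[i]
      warning(sprintf(
        "boxes %d and an earlier one claim cell (%d,%d) anchor %d; keeping the larger",
        i, row, col, j), call. = FALSE)
      if (new_area <= old_area) next
    }
    slot <- numeric(5L + n_classes)
    slot[1] <- cx * S - col
    slot[2] <- cy * S - row
    slot[3] <- labels$w[i]
    slot[4] <- labels$h[i]
    slot[5] <- 1
    slot[5L + labels$class_id[i] + 1L] <- 1
    tensor[row + 1L, col + 1L, j, ] <- slot
    obj[row + 1L, col + 1L, j] <- TRUE
  }
  structure(list(tensor = tensor, obj = obj, S = S, B = B,
                 n_classes = n_classes), class = "grid_target")
}

check_pred <- function(pred, target) {
  stopifnot(inherits(target, "grid_target"))
  if (!is.array(pred) || !identical(dim(pred), dim(target$tensor)))
    stop("prediction tensor shape does not match the target grid",
         call. = FALSE)
  invisible(pred)
}

#' Coordinate (bounding-box) loss
#'
#' Sum over responsible anchor slots of the squared centre-offset errors
#' plus the squared errors of the square roots of width and height, each
#' weighted by `alpha_coord`. The square roots damp the penalty on large
#' boxes relative to small ones; widths and heights are normalized to
#' the image so the roots are defined on `[0, 1]`.
#'
#' @param pred Prediction tensor shaped like the target's (decoded
#'   values: offsets in `[0, 1]`, sizes as image fractions).
#' @param target A [encode_targets()] result.
#' @param weights See [loss_weights()].
#' @return A non-negative number.
#' @export
coord_loss <- function(pred, target, weights = loss_weights()) {
  check_pred(pred, target)
  m <- target$obj
  if (!any(m)) return(0)
  p <- target$tensor
  sel <- function(a, ch) a[, , , ch, drop = FALSE][m]
  pw <- sel(pred, 3); ph <- sel(pred, 4)
  tw <- sel(p, 3);    th <- sel(p, 4)
  if (any(pw < 0) || any(ph < 0) || any(tw < 0) || any(th < 0))
    stop("negative box dimensions in coordinate loss", call. = FALSE)
  xy <- sum((sel(p, 1) - sel(pred, 1))^2 + (sel(p, 2) - sel(pred, 2))^2)
  wh <- sum((sqrt(tw) - sqrt(pw))^2 + (sqrt(th) - sqrt(ph))^2)
  weights$alpha_coord * xy + weights$alpha_coord * wh
}

#' Confidence (objectness) loss
#'
#' Squared confidence error summed over responsible slots (target 1)
#' plus `alpha_noobj` times the squared error over all non-responsible
#' slots (target 0).
#'
#' @inheritParams coord_loss
#' @return A non-negative number.
#' @export
conf_loss <- function(pred, target, weights = loss_weights()) {
  check_pred(pred, target)
  m <- target$obj
  cdiff <- (target$tensor[, , , 5] - pred[, , , 5])^2
  sum(cdiff[m]) + weights$alpha_noobj * sum(cdiff[!m])
}

#' Classification loss
#'
#' Sum over grid cells containing an object of the squared class-score
#' errors. The class term is evaluated once per occupied cell, at its
#' responsible anchor slot (when several objects share a cell, at the
#' responsible slot holding the largest target box).
#'
#' @inheritParams coord_loss
#' @return A non-negative number.
#' @export
class_loss <- function(pred, target) {
  check_pred(pred, target)
  if (target$n_classes < 1L || !any(target$obj)) return(0)
  total <- 0
  S <- target$S
  for (r in seq_len(S)) for (cc in seq_len(S)) {
    js <- which(target$obj[r, cc, ])
    if (length(js) == 0L) next
    if (length(js) > 1L) {
      areas <- target$tensor[r, cc, js, 3] * target$tensor[r, cc, js, 4]
      js <- js[which.max(areas)]
    }
    ch <- 6:(5 + target$n_classes)
    total <- total +
      sum((target$tensor[r, cc, js, ch] - pred[r, cc, js, ch])^2)
  }
  total
}

#' Total grid detection loss
#'
#' Sum of the coordinate, confidence and classification parts:
#' `L = L1 + L2 + L3`. Zero exactly when the prediction matches the
#' target on every contributing slot.
#'
#' @inheritParams coord_loss
#' @return A list with components `coord`, `conf`, `class`, `total`.
#' @export
total_loss <- function(pred, target, weights = loss_weights()) {
  l1 <- coord_loss(pred, target, weights)
  l2 <- conf_loss(pred, target, weights)
  l3 <- class_loss(pred, target)
  list(coord = l1, conf = l2, class = l3, total = l1 + l2 + l3)
}
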