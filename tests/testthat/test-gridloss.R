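anchors3 <- matrix(c(0.1, 0.15, 0.3, 0.3, 0.6, 0.4), ncol = 2, byrow = TRUE)

test_that("targets land in the half-open cell containing the box centre", {
  lab <- data.frame(class_id = 0L, cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  t <- encode_targets(lab, 2, anchors3, 2)
  idx <- which(t$obj, arr.ind = TRUE)
  expect_equal(unname(idx[1, 1:2]) - 1L, c(1L, 1L))  # 0-based (row, col)
  expect_equal(sum(t$obj), 1)

  lab <- data.frame(class_id = 1L, cx = 0.3, cy = 0.7, w = 0.2, h = 0.2)
  t <- encode_targets(lab, 19, anchors3, 2)
  idx <- which(t$obj, arr.ind = TRUE)
  expect_equal(unname(idx[1, 2]) - 1L, 5L)   # col = floor(0.3 * 19)
  expect_equal(unname(idx[1, 1]) - 1L, 13L)  # row = floor(0.7 * 19)
  slot <- t$tensor[idx[1, 1], idx[1, 2], idx[1, 3], ]
  expect_equal(slot[1], 0.3 * 19 - 5, tolerance = 1e-12)  # x offset 0.7
  expect_equal(slot[2], 0.7 * 19 - 13, tolerance = 1e-12) # y offset 0.3
  expect_equal(slot[3:5], c(0.2, 0.2, 1))
  expect_equal(slot[6:7], c(0, 1))  # one-hot class 1
})

test_that("the responsible anchor maximizes co-centred IoU", {
  lab <- data.frame(class_id = 0L, cx = 0.5, cy = 0.5, w = 0.58, h = 0.42)
  t <- encode_targets(lab, 3, anchors3, 1)
  idx <- which(t$obj, arr.ind = TRUE)
  expect_equal(unname(idx[1, 3]),
               which.max(wh_iou(matrix(c(0.58, 0.42), ncol = 2), anchors3)))
})

test_that("conflicting boxes on one slot keep the larger with a warning", {
  lab <- data.frame(class_id = c(0L, 1L),
                    cx = c(0.51, 0.52), cy = c(0.51, 0.52),
                    w = c(0.30, 0.32), h = c(0.30, 0.32))
  expect_warning(t <- encode_targets(lab, 2, anchors3, 2), "claim")
  expect_equal(sum(t$obj), 1)
  idx <- which(t$obj, arr.ind = TRUE)
  expect_equal(t$tensor[idx[1, 1], idx[1, 2], idx[1, 3], 3], 0.32)
})

single_cell_case <- function() {
  lab <- data.frame(class_id = 0L, cx = 0.55, cy = 0.55, w = 0.25, h = 0.3)
  target <- encode_targets(lab, 2, anchors3, 2)
  pred <- target$tensor
  list(target = target, pred = pred,
       idx = which(target$obj, arr.ind = TRUE))
}

test_that("coordinate loss matches the hand-arithmetic single-cell
           cases", {
  cs <- single_cell_case()
  expect_equal(coord_loss(cs$pred, cs$target), 0)
  p <- cs$pred
  p[cs$idx[1], cs$idx[2], cs$idx[3], 1] <-
    p[cs$idx[1], cs$idx[2], cs$idx[3], 1] - 0.1
  expect_equal(coord_loss(p, cs$target), 5 * 0.01)      # x off by 0.1
  # width 0.25 predicted as 0.16: 5 * (0.5 - 0.4)^2
  cs2 <- single_cell_case()
  p2 <- cs2$pred
  p2[cs2$idx[1], cs2$idx[2], cs2$idx[3], 3] <- 0.16
  expect_equal(coord_loss(p2, cs2$target), 5 * (0.5 - 0.4)^2)
  p2[cs2$idx[1], cs2$idx[2], cs2$idx[3], 3] <- -0.1
  expect_error(coord_loss(p2, cs2$target), "negative")
})

test_that("confidence loss weighs responsible and background slots as
           printed", {
  cs <- single_cell_case()
  expect_equal(conf_loss(cs$pred, cs$target), 0)
  p <- cs$pred
  p[cs$idx[1], cs$idx[2], cs$idx[3], 5] <- 0.8
  expect_equal(conf_loss(p, cs$target), (0.8 - 1)^2)     # 0.04
  cs2 <- single_cell_case()
  p2 <- cs2$pred
  bg <- which(!cs2$target$obj, arr.ind = TRUE)[1, ]
  p2[bg[1], bg[2], bg[3], 5] <- 0.2
  expect_equal(conf_loss(p2, cs2$target), 0.5 * 0.04)    # 0.02
})

test_that("classification loss sums squared class-score errors per
           occupied cell", {
  cs <- single_cell_case()
  expect_equal(class_loss(cs$pred, cs$target), 0)
  p <- cs$pred
  p[cs$idx[1], cs$idx[2], cs$idx[3], 6:7] <- c(0.6, 0.4)
  expect_equal(class_loss(p, cs$target), 0.16 + 0.16)    # target (1, 0)
  empty <- encode_targets(
    data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
               w = numeric(0), h = numeric(0)), 2, anchors3, 2)
  expect_equal(class_loss(empty$tensor, empty), 0)
})

test_that("total loss decomposes and reproduces the combined worked
           example", {
  cs <- single_cell_case()
  p <- cs$pred
  p[cs$idx[1], cs$idx[2], cs$idx[3], 1] <-
    p[cs$idx[1], cs$idx[2], cs$idx[3], 1] - 0.1   # L1 = 0.05
  p[cs$idx[1], cs$idx[2], cs$idx[3], 5] <- 0.8    # L2 += 0.04
  bg <- which(!cs$target$obj, arr.ind = TRUE)[1, ]
  p[bg[1], bg[2], bg[3], 5] <- 0.2                # L2 += 0.02
  l <- total_loss(p, cs$target)
  expect_equal(l$coord, 0.05)
  expect_equal(l$conf, 0.06)
  expect_equal(l$class, 0)
  expect_equal(l$total, 0.11)
  # doubling alpha_coord doubles only the coordinate part
  l2 <- total_loss(p, cs$target, loss_weights(alpha_coord = 10))
  expect_equal(l2$coord, 2 * l$coord)
  expect_equal(l2$conf, l$conf)
})

test_that("loss equals a scalar-loop oracle on random small grids", {
  set.seed(37)
  for (rep in 1:8) {
    S <- sample(2:3, 1); B <- sample(1:2, 1); C <- sample(1:3, 1)
    anch <- cbind(runif(B, 0.05, 0.6), runif(B, 0.05, 0.6))
    n_box <- sample(1:3, 1)
    lab <- data.frame(class_id = sample(0:(C - 1), n_box, replace = TRUE),
                      cx = runif(n_box, 0.1, 0.9),
                      cy = runif(n_box, 0.1, 0.9),
                      w = runif(n_box, 0.05, 0.3),
                      h = runif(n_box, 0.05, 0.3))
    target <- suppressWarnings(encode_targets(lab, S, anch, C))
    pred <- array(runif(S * S * B * (5 + C)), dim = c(S, S, B, 5 + C))
    ours <- total_loss(pred, target)
    ref <- naive_grid_loss(pred, target)
    expect_equal(ours$coord, ref$coord, tolerance = 1e-12)
    expect_equal(ours$conf, ref$conf, tolerance = 1e-12)
    expect_equal(ours$class, ref$class, tolerance = 1e-12)
    expect_equal(ours$total, ref$total, tolerance = 1e-12)
    expect_equal(ours$total, ours$coord + ours$conf + ours$class,
                 tolerance = 1e-12)
    expect_true(all(unlist(ours) >= 0))
  }
})

test_that("zero loss iff the prediction matches every contributing
           slot", {
  cs <- single_cell_case()
  expect_equal(total_loss(cs$pred, cs$target)$total, 0)
  p <- cs$pred
  p[1, 1, 1, 5] <- p[1, 1, 1, 5] + 0.01
  expect_gt(total_loss(p, cs$target)$total, 0)
})
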