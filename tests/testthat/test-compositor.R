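obj_grid <- list(rotation = seq(0, 345, 15), zoom = seq(0.5, 1.5, 0.1),
                 shift = seq(-100, 100, 15))

test_that("object transforms are reproducible and stay on their grids", {
  set.seed(1); s1 <- sample_object_transform()
  set.seed(1); s2 <- sample_object_transform()
  expect_identical(s1, s2)
  set.seed(2)
  draws <- replicate(500, sample_object_transform(), simplify = FALSE)
  expect_true(all(vapply(draws, `[[`, numeric(1), "rotation_deg")
                  %in% obj_grid$rotation))
  zooms <- vapply(draws, `[[`, numeric(1), "zoom")
  expect_true(all(vapply(zooms, function(z)
    any(abs(z - obj_grid$zoom) < 1e-9), logical(1))))
  shifts <- t(vapply(draws, `[[`, integer(2), "shift_px"))
  expect_true(all(shifts %in% obj_grid$shift))
})

test_that("ten thousand draws cover the whole 24-value rotation grid", {
  set.seed(3)
  rots <- replicate(1e4, sample_object_transform()$rotation_deg)
  expect_setequal(unique(rots), obj_grid$rotation)
})

test_that("base transforms keep soil coverage: rotation 0/180, zoom >= 1,
           no shift", {
  set.seed(4)
  draws <- replicate(300, sample_base_transform(), simplify = FALSE)
  expect_true(all(vapply(draws, `[[`, numeric(1), "rotation_deg")
                  %in% c(0, 180)))
  expect_true(all(vapply(draws, `[[`, numeric(1), "zoom") >= 1 - 1e-9))
  expect_true(all(vapply(draws, `[[`, numeric(1), "zoom") <= 1.8 + 1e-9))
  expect_true(all(t(vapply(draws, `[[`, integer(2), "shift_px")) == 0L))
})

test_that("apply_transform: identity is exact, 180 degrees is an
           involution, flips reverse axes", {
  scene <- generate_field_fixture(8, c(64, 64), 1, 0)
  img <- scene$image; mask <- scene$masks[[1]]
  idt <- apply_transform(img, mask, transform_spec())
  expect_identical(idt$image, img)
  expect_identical(idt$mask, mask)
  half <- transform_spec(rotation_deg = 180)
  twice <- apply_transform(img, mask, half)
  twice <- apply_transform(twice$image, twice$mask, half)
  expect_identical(twice$image, img)
  expect_identical(twice$mask, mask)
  hf <- apply_transform(img, mask, transform_spec(flip = "horizontal"))
  expect_identical(hf$image, img[, 64:1, , drop = FALSE])
  expect_identical(hf$mask, mask[, 64:1])
  vf <- apply_transform(img, mask, transform_spec(flip = "vertical"))
  expect_identical(vf$image, img[64:1, , , drop = FALSE])
})

test_that("apply_transform fills exposed regions black/false", {
  img <- flat_image(32, 32, c(200, 200, 200))
  mask <- matrix(TRUE, 32, 32)
  sh <- apply_transform(img, mask, transform_spec(shift_px = c(16L, 0L)))
  expect_true(all(sh$image[, 1:16, ] == 0))
  expect_false(any(sh$mask[, 1:16]))
  expect_true(all(sh$image[, 17:32, ] == 200))
  expect_true(all(sh$mask[, 17:32]))
})

test_that("paste replaces exactly the masked pixels", {
  base <- flat_image(2, 2, c(10, 20, 30))
  obj <- flat_image(2, 2, c(200, 210, 220))
  expect_identical(paste_object(base, obj, matrix(FALSE, 2, 2)), base)
  expect_identical(paste_object(base, obj, matrix(TRUE, 2, 2)), obj)
  checker <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  out <- paste_object(base, obj, checker)
  for (ch in 1:3) {
    expected <- base[, , ch]
    expected[checker] <- obj[, , ch][checker]
    expect_identical(out[, , ch], expected)
  }
  expect_error(paste_object(base, flat_image(3, 2, c(0, 0, 0)),
                            matrix(TRUE, 2, 2)), "dimensions")
})

test_that("gamma correction: fixed points, identity, worked value,
           monotonicity, domain error", {
  ramp <- array(rep(0:255, 3), dim = c(1, 256, 3))
  expect_identical(gamma_correct(ramp, 1.0), array(as.integer(ramp),
                                                   dim = dim(ramp)))
  for (g in c(0.5, 0.7, 1.3, 1.5)) {
    out <- gamma_correct(ramp, g)
    expect_equal(out[1, 1, 1], 0L)
    expect_equal(out[1, 256, 1], 255L)
    expect_true(all(diff(out[1, , 1]) >= 0))
  }
  expect_equal(gamma_correct(flat_image(1, 1, c(64, 64, 64)), 0.5)[1, 1, 1],
               128L)
  expect_error(gamma_correct(ramp, 0), "positive")
  expect_error(gamma_correct(ramp, -1), "positive")
})

test_that("bbox_from_mask returns tight half-open boxes", {
  m <- matrix(FALSE, 10, 10)
  expect_null(bbox_from_mask(m))
  m[4, 6] <- TRUE  # 0-based (row 3, col 5)
  expect_equal(bbox_from_mask(m),
               c(xmin = 5, ymin = 3, xmax = 6, ymax = 4))
  m <- matrix(FALSE, 10, 10)
  m[3:5, 2:8] <- TRUE  # rows 2-4, cols 1-7 in 0-based terms
  expect_equal(bbox_from_mask(m),
               c(xmin = 1, ymin = 2, xmax = 8, ymax = 5))
})

test_that("compose_pair is deterministic under a seed and labels both
           plants", {
  beet <- make_sources(1, 0L, seed0 = 200L)[[1]]
  weed <- make_sources(1, 1L, seed0 = 300L)[[1]]
  r1 <- compose_pair(beet, weed, seed = 17)
  r2 <- compose_pair(beet, weed, seed = 17)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$labels), 2)
  expect_setequal(r1$labels$class_id, c(0L, 1L))
  # every label box inside the unit square
  expect_true(all(r1$labels$cx - r1$labels$w / 2 >= -1e-9))
  expect_true(all(r1$labels$cx + r1$labels$w / 2 <= 1 + 1e-9))
  expect_true(all(r1$labels$cy - r1$labels$h / 2 >= -1e-9))
  expect_true(all(r1$labels$cy + r1$labels$h / 2 <= 1 + 1e-9))
})

test_that("pre-gamma composite equals the transformed base outside the
           pasted mask", {
  beet <- make_sources(1, 0L, seed0 = 210L)[[1]]
  weed <- make_sources(1, 1L, seed0 = 310L)[[1]]
  rec <- compose_pair(beet, weed, seed = 23)
  pv <- rec$provenance
  tb <- apply_transform(beet$image, beet$mask, pv$base_spec)
  to <- apply_transform(weed$image, weed$mask, pv$object_spec)
  pre_gamma <- paste_object(tb$image, to$image, to$mask)
  for (ch in 1:3) {
    outside <- pre_gamma[, , ch][!to$mask]
    expect_identical(outside, tb$image[, , ch][!to$mask])
  }
  expect_identical(gamma_correct(pre_gamma, pv$gamma), rec$image)
})

test_that("compose_pair errors when no transform keeps the object
           visible", {
  beet <- make_sources(1, 0L, seed0 = 220L)[[1]]
  weed <- make_sources(1, 1L, seed0 = 320L)[[1]]
  # full visibility is unattainable once the sampled zoom shrinks or the
  # shift clips the object, so a tight retry budget must exhaust
  strict <- compose_params(min_visible_frac = 1, max_retries = 2)
  expect_error(compose_pair(beet, weed, params = strict, seed = 1),
               "no admissible transform")
})

test_that("dataset schedule reproduces the reference pair arithmetic", {
  sched <- dataset_schedule(51, 26, 269, seed = 9)
  expect_equal(sum(sched$kind == "mixed"), 1326)
  expect_equal(sum(sched$kind == "weed_weed"), 676)
  expect_equal(sum(sched$kind == "beet_beet"), 269)
  expect_equal(nrow(sched), 2271)
  bb <- sched[sched$kind == "beet_beet", c("base_idx", "obj_idx")]
  expect_equal(nrow(unique(bb)), 269)  # without replacement
  expect_error(dataset_schedule(3, 2, 10), "beet-beet")
})

test_that("generate_dataset writes the scheduled composites
           reproducibly", {
  beets <- make_sources(3, 0L, hw = c(128L, 128L), seed0 = 400L)
  weeds <- make_sources(2, 1L, hw = c(128L, 128L), seed0 = 500L)
  # the pixel shift grid spans +/-100 px, large relative to this small
  # test canvas, so allow generous transform resampling
  pp <- compose_params(max_retries = 100)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_dataset(beets, weeds, n_beet_beet = 2, seed = 99,
                         out_dir = d1, params = pp)
  m2 <- generate_dataset(beets, weeds, n_beet_beet = 2, seed = 99,
                         out_dir = d2, params = pp)
  expect_equal(nrow(m1), 3 * 2 + 2 * 2 + 2)  # mixed + weed-weed + beet-beet
  expect_true(all(file.exists(m1$image)))
  expect_true(all(file.exists(m1$labels)))
  # identical runs modulo output directory
  expect_equal(m1[setdiff(names(m1), c("image", "labels"))],
               m2[setdiff(names(m2), c("image", "labels"))])
  h1 <- unname(tools::md5sum(m1$image))
  h2 <- unname(tools::md5sum(m2$image))
  expect_identical(h1, h2)
  lab <- read_labels(m1$labels[1], c(128, 128))$labels
  expect_equal(nrow(lab), 2)
})
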