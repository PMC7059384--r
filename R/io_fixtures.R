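#' Read an image file as an 8-bit RGB array
#'
#' PNG files are read with the png package; JPEG falls back to EBImage
#' when installed. Grayscale images are replicated to three channels,
#' alpha channels dropped.
#'
#' @param path Image file path.
#' @return An `H x W x 3` integer array in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("reading JPEG requires the EBImage package", call. = FALSE)
    x <- EBImage::imageData(EBImage::readImage(path))
    x <- aperm(x, c(2, 1, 3))  # EBImage stores x-major
  } else stop("unsupported image format: .", ext, call. = FALSE)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), dim = c(dim(x), 3))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  array(as.integer(round(x * 255)), dim = dim(x))
}

#' Write an 8-bit RGB array as PNG
#'
#' @param img RGB image array (see [rgb_image()]).
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- rgb_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Write a binary mask as a single-channel PNG (0/255)
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Read a 0/255 PNG mask back to a logical matrix
#'
#' @param path Mask file path.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x > 0.5
}

#' Convert normalized label records to pixel-corner boxes
#'
#' Darknet-normalized `(cx, cy, w, h)` become half-open 0-based pixel
#' boxes; boundaries are rounded half-away-from-zero so the conversion
#' is exact at simple fractions.
#'
#' @param labels Data frame with `cx`, `cy`, `w`, `h` in `[0, 1]` (and
#'   any other columns, carried through).
#' @param image_hw Integer `c(H, W)` of the image the labels refer to.
#' @return Data frame with columns `xmin`, `ymin`, `xmax`, `ymax` (plus
#'   `class_id` when present in `labels`).
#' @export
labels_to_boxes <- function(labels, image_hw) {
  h <- image_hw[1]; w <- image_hw[2]
  out <- data.frame(
    xmin = round_half_away((labels$cx - labels$w / 2) * w),
    ymin = round_half_away((labels$cy - labels$h / 2) * h),
    xmax = round_half_away((labels$cx + labels$w / 2) * w),
    ymax = round_half_away((labels$cy + labels$h / 2) * h)
  )
  if ("class_id" %in% names(labels))
    out <- cbind(class_id = labels$class_id, out)
  out
}

#' Convert pixel-corner boxes to normalized label records
#'
#' @param boxes Data frame with `xmin`, `ymin`, `xmax`, `ymax` (0-based
#'   half-open pixels) and optionally `class_id`.
#' @inheritParams labels_to_boxes
#' @return Data frame with `class_id` (if present), `cx`, `cy`, `w`,
#'   `h`.
#' @export
boxes_to_labels <- function(boxes, image_hw) {
  h <- image_hw[1]; w <- image_hw[2]
  out <- data.frame(
    cx = (boxes$xmin + boxes$xmax) / 2 / w,
    cy = (boxes$ymin + boxes$ymax) / 2 / h,
    w = (boxes$xmax - boxes$xmin) / w,
    h = (boxes$ymax - boxes$ymin) / h
  )
  if ("class_id" %in% names(boxes))
    out <- cbind(class_id = boxes$class_id, out)
  out
}

#' Read a darknet-style label file
#'
#' Each line holds `class_id cx cy w h`, whitespace-separated, with
#' coordinates normalized to the image size. Malformed lines and
#' out-of-range values raise errors naming the offending line.
#'
#' @param path Label file path.
#' @param image_hw Integer `c(H, W)` for the pixel conversion.
#' @return A list with `labels` (normalized records) and `boxes` (their
#'   pixel-corner conversions, see [labels_to_boxes()]).
#' @export
read_labels <- function(path, image_hw) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 5L || anyNA(vals))
      stop(sprintf("line %d of %s: expected 5 numbers, got '%s'",
                   i, path, lines[i]), call. = FALSE)
    if (vals[1] < 0 || vals[1] != floor(vals[1]))
      stop(sprintf("line %d of %s: class id must be a non-negative integer",
                   i, path), call. = FALSE)
    eps <- 1e-6
    if (any(vals[2:5] < -eps) || any(vals[2:5] > 1 + eps) ||
        vals[2] - vals[4] / 2 < -eps || vals[2] + vals[4] / 2 > 1 + eps ||
        vals[3] - vals[5] / 2 < -eps || vals[3] + vals[5] / 2 > 1 + eps)
      stop(sprintf("line %d of %s: box outside the unit square", i, path),
           call. = FALSE)
    recs[[i]] <- data.frame(class_id = as.integer(vals[1]), cx = vals[2],
                            cy = vals[3], w = vals[4], h = vals[5])
  }
  labels <- if (length(recs)) do.call(rbind, recs) else
    data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
               w = numeric(0), h = numeric(0))
  list(labels = labels, boxes = labels_to_boxes(labels, image_hw))
}

#' Write label records in darknet format
#'
#' One record per line, in the given order, `class cx cy w h` with six
#' decimal places.
#'
#' @param labels Data frame with `class_id`, `cx`, `cy`, `w`, `h`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  lines <- if (nrow(labels) == 0L) character(0) else
    sprintf("%d %.6f %.6f %.6f %.6f", labels$class_id,
            labels$cx, labels$cy, labels$w, labels$h)
  writeLines(lines, path)
  invisible(path)
}

#' Fixture generator parameters
#'
#' Tunables of the procedural field-scene generator: soil colour and
#' texture amplitude, plant colour, geometry ranges (as fractions of the
#' short image side) for the single-ellipse "crop" class and the
#' multi-lobe "weed" class, and placement limits.
#'
#' @param soil_rgb Mean soil colour (8-bit RGB).
#' @param soil_noise_amp Amplitude of the low-frequency luminance
#'   texture, intensity units.
#' @param noise_cells Side of the coarse noise grid upscaled onto the
#'   image.
#' @param green_rgb Mean plant colour.
#' @param green_jitter Per-pixel plant colour jitter, intensity units.
#' @param beet_radius_frac Range of the crop ellipse semi-major axis.
#' @param weed_lobe_radius_frac Range of weed lobe radii.
#' @param weed_lobes Candidate lobe counts per weed.
#' @param weed_spread_frac Radius over which weed lobes scatter.
#' @param margin_frac Placement margin from the canvas border.
#' @param max_place_tries Placement attempts per plant before erroring.
#' @return A parameter list.
#' @export
fixture_params <- function(soil_rgb = c(120, 92, 64), soil_noise_amp = 20,
                           noise_cells = 8L, green_rgb = c(62, 150, 58),
                           green_jitter = 12,
                           beet_radius_frac = c(0.10, 0.16),
                           weed_lobe_radius_frac = c(0.022, 0.035),
                           weed_lobes = 3:5, weed_spread_frac = 0.055,
                           margin_frac = 0.05, max_place_tries = 200L) {
  list(soil_rgb = soil_rgb, soil_noise_amp = soil_noise_amp,
       noise_cells = as.integer(noise_cells), green_rgb = green_rgb,
       green_jitter = green_jitter, beet_radius_frac = beet_radius_frac,
       weed_lobe_radius_frac = weed_lobe_radius_frac,
       weed_lobes = weed_lobes, weed_spread_frac = weed_spread_frac,
       margin_frac = margin_frac,
       max_place_tries = as.integer(max_place_tries))
}

#' Generate a procedural field scene with ground truth
#'
#' Emulates a top-down plant-on-soil photograph at toy scale: a brown
#' background with low-frequency luminance texture, class-0 plants as
#' single large rotated green ellipses (crop-like rosettes) and class-1
#' plants as clusters of 3-5 small green lobes (a distinct shape
#' signature), with exact per-plant masks and tight boxes. Colours are
#' chosen so the excess-green index separates plants from soil. Plant
#' masks are mutually disjoint by construction (placements that would
#' overlap are rejected and resampled). The scene is a pure function of
#' `(seed, hw, counts, params)`.
#'
#' @param seed Integer seed.
#' @param hw Integer `c(H, W)`, at least 64 each.
#' @param n_beet,n_weed Plant counts per class.
#' @param params See [fixture_params()].
#' @return A list of class `"field_scene"`: `image`, `masks` (list of
#'   logical matrices, one per plant), `labels` (darknet-normalized
#'   data frame), `seed`, `hw`.
#' @export
generate_field_fixture <- function(seed, hw = c(256L, 256L), n_beet = 2L,
                                   n_weed = 2L, params = fixture_params()) {
  hw <- as.integer(hw)
  stopifnot(length(hw) == 2L, all(hw >= 64L), n_beet >= 0, n_weed >= 0)
  with_local_seed(seed, {
    h <- hw[1]; w <- hw[2]; side <- min(h, w)
    # soil: shared low-frequency luminance + fine per-pixel jitter
    lum <- upscale_bilinear(
      matrix(stats::runif(params$noise_cells^2, -params$soil_noise_amp,
                          params$soil_noise_amp),
             params$noise_cells, params$noise_cells), h, w)
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3)
      img[, , ch] <- params$soil_rgb[ch] + lum +
        matrix(stats::runif(h * w, -5, 5), h, w)

    xg <- matrix(seq_len(w), h, w, byrow = TRUE)
    yg <- matrix(seq_len(h), h, w)
    classes <- c(rep(0L, n_beet), rep(1L, n_weed))
    masks <- list()
    occupied <- matrix(FALSE, h, w)
    for (p in seq_along(classes)) {
      placed <- FALSE
      for (try in seq_len(params$max_place_tries)) {
        if (classes[p] == 0L) {
          a <- stats::runif(1, params$beet_radius_frac[1],
                            params$beet_radius_frac[2]) * side
          b <- a * stats::runif(1, 0.65, 0.95)
          th <- stats::runif(1, 0, pi)
          ext <- max(a, b)
          cx <- stats::runif(1, ext + params$margin_frac * w,
                             w - ext - params$margin_frac * w)
          cy <- stats::runif(1, ext + params$margin_frac * h,
                             h - ext - params$margin_frac * h)
          u <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
          v <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
          m <- (u / a)^2 + (v / b)^2 <= 1
        } else {
          nl <- sample(params$weed_lobes, 1L)
          spread <- params$weed_spread_frac * side
          rmax <- params$weed_lobe_radius_frac[2] * side
          ext <- spread + rmax
          cx <- stats::runif(1, ext + params$margin_frac * w,
                             w - ext - params$margin_frac * w)
          cy <- stats::runif(1, ext + params$margin_frac * h,
                             h - ext - params$margin_frac * h)
          m <- matrix(FALSE, h, w)
          for (l in seq_len(nl)) {
            ang <- stats::runif(1, 0, 2 * pi)
            rad <- stats::runif(1, 0, spread)
            lx <- cx + rad * cos(ang); ly <- cy + rad * sin(ang)
            lr <- stats::runif(1, params$weed_lobe_radius_frac[1],
                               params$weed_lobe_radius_frac[2]) * side
            m <- m | ((xg - lx)^2 + (yg - ly)^2 <= lr^2)
          }
        }
        if (!any(m) || any(m & occupied)) next
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf(
          "could not place plant %d without overlap in %d tries",
          p, params$max_place_tries), call. = FALSE)
      occupied <- occupied | m
      masks[[p]] <- m
      npx <- sum(m)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[m] <- params$green_rgb[ch] +
          stats::runif(npx, -params$green_jitter, params$green_jitter)
        img[, , ch] <- plane
      }
    }
    img <- array(as.integer(pmin(255, pmax(0, round(img)))), dim = c(h, w, 3))
    boxes <- do.call(rbind, lapply(masks, bbox_from_mask))
    labels <- if (length(masks)) {
      cbind(class_id = classes,
            boxes_to_labels(as.data.frame(boxes), hw))
    } else data.frame(class_id = integer(0), cx = numeric(0),
                      cy = numeric(0), w = numeric(0), h = numeric(0))
    structure(list(image = img, masks = masks, labels = labels,
                   seed = seed, hw = hw), class = "field_scene")
  })
}

#' Write a field scene to disk
#'
#' Emits `<stem>.png` (image), `<stem>.txt` (darknet labels) and
#' `<stem>_mask_<i>.png` per plant mask.
#'
#' @param scene A [generate_field_fixture()] result.
#' @param out_dir Output directory (created if missing).
#' @param stem File-name stem.
#' @return Named list of written paths, invisibly.
#' @export
write_field_fixture <- function(scene, out_dir, stem = "scene") {
  stopifnot(inherits(scene, "field_scene"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  img <- file.path(out_dir, paste0(stem, ".png"))
  lbl <- file.path(out_dir, paste0(stem, ".txt"))
  write_image(scene$image, img)
  write_labels(scene$labels, lbl)
  maskp <- character(length(scene$masks))
  for (i in seq_along(scene$masks)) {
    maskp[i] <- file.path(out_dir, sprintf("%s_mask_%d.png", stem, i))
    write_mask(scene$masks[[i]], maskp[i])
  }
  invisible(list(image = img, labels = lbl, masks = maskp))
}
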