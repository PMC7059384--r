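#' Geometric transform specification
#'
#' A transform applied to a plant object (or base image) during
#' cut-and-paste compositing: rotation about the canvas centre, isotropic
#' zoom about the centre, integer pixel shift, and an optional axis flip,
#' applied in that fixed order.
#'
#' @param rotation_deg Rotation angle in degrees (counter-clockwise in
#'   image axes).
#' @param zoom Positive magnification factor.
#' @param shift_px Integer vector `c(dx, dy)`: horizontal and vertical
#'   shift in pixels (positive = right/down).
#' @param flip One of `"none"`, `"horizontal"`, `"vertical"`.
#' @return A list of class `"transform_spec"`.
#' @export
transform_spec <- function(rotation_deg = 0, zoom = 1,
                           shift_px = c(0L, 0L), flip = "none") {
  stopifnot(is.numeric(rotation_deg), length(rotation_deg) == 1L,
            is.numeric(zoom), length(zoom) == 1L, zoom > 0,
            length(shift_px) == 2L)
  flip <- match.arg(flip, c("none", "horizontal", "vertical"))
  structure(list(rotation_deg = rotation_deg, zoom = zoom,
                 shift_px = as.integer(shift_px), flip = flip),
            class = "transform_spec")
}

# parameter grids for the compositing pipeline (all sampling is uniform
# and independent over these sets)
object_grids <- function() {
  list(rotation = seq(0, 345, by = 15),
       zoom     = seq(0.5, 1.5, by = 0.1),
       shift    = seq(-100L, 100L, by = 15L),
       flip     = c("none", "horizontal", "vertical"))
}
base_grids <- function() {
  list(rotation = c(0, 180),
       zoom     = seq(1.0, 1.8, by = 0.1),
       flip     = c("none", "horizontal", "vertical"))
}

#' Sample a transform for a pasted plant object
#'
#' Draws each component independently and uniformly from the object
#' grids: rotation 0-345 degrees in 15-degree steps, zoom 0.5-1.5 in 0.1
#' steps, shift -100..100 px in 15-px steps (both axes), flip from
#' \{none, horizontal, vertical\}. Uses the current R random stream;
#' seed the generator (or the calling pipeline) for reproducibility.
#'
#' @return A [transform_spec()].
#' @export
sample_object_transform <- function() {
  g <- object_grids()
  transform_spec(
    rotation_deg = sample(g$rotation, 1L),
    zoom = sample(g$zoom, 1L),
    shift_px = c(sample(g$shift, 1L), sample(g$shift, 1L)),
    flip = sample(g$flip, 1L)
  )
}

#' Sample a transform for a base image
#'
#' Base images keep their soil background, so the grids are restricted:
#' rotation 0 or 180 degrees, zoom 1.0-1.8 in 0.1 steps (never shrinking,
#' so the canvas stays covered), no shift, flip from
#' \{none, horizontal, vertical\}.
#'
#' @return A [transform_spec()].
#' @export
sample_base_transform <- function() {
  g <- base_grids()
  transform_spec(
    rotation_deg = sample(g$rotation, 1L),
    zoom = sample(g$zoom, 1L),
    shift_px = c(0L, 0L),
    flip = sample(g$flip, 1L)
  )
}

#' Apply a geometric transform to an image and its mask
#'
#' Warps by inverse mapping on a canvas of the original size: rotation
#' and zoom about the canvas centre, then shift, then flip. The image is
#' resampled bilinearly, the mask by nearest neighbour; regions exposed
#' by the transform are filled black in the image and `FALSE` in the
#' mask. The identity spec reproduces the input exactly.
#'
#' @param image An RGB image array.
#' @param mask An `H x W` logical matrix matching `image`.
#' @param spec A [transform_spec()].
#' @return A list with elements `image` and `mask`.
#' @export
apply_transform <- function(image, mask, spec) {
  image <- rgb_image(image)
  stopifnot(is.logical(mask), inherits(spec, "transform_spec"))
  h <- dim(image)[1]; w <- dim(image)[2]
  if (!all(dim(mask) == c(h, w)))
    stop("image and mask dimensions differ", call. = FALSE)

  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  xo <- matrix(seq_len(w), h, w, byrow = TRUE)
  yo <- matrix(seq_len(h), h, w)

  # undo flip
  if (spec$flip == "horizontal") xo <- w + 1 - xo
  if (spec$flip == "vertical")   yo <- h + 1 - yo
  # undo shift
  xo <- xo - spec$shift_px[1]
  yo <- yo - spec$shift_px[2]
  # undo zoom then rotation about the centre
  dx <- (xo - cx) / spec$zoom
  dy <- (yo - cy) / spec$zoom
  ct <- cospi(spec$rotation_deg / 180)
  st <- sinpi(spec$rotation_deg / 180)
  xs <- cx + ct * dx + st * dy
  ys <- cy - st * dx + ct * dy

  out <- array(0L, dim = dim(image))
  for (ch in 1:3) {
    v <- sample_bilinear(image[, , ch], xs, ys)
    out[, , ch] <- as.integer(pmin(255, pmax(0, round(v))))
  }
  list(image = out, mask = sample_nearest(mask, xs, ys))
}

#' Paste a masked object onto a base image
#'
#' The object mask acts as a logic control image: wherever it is `TRUE`
#' the base pixel is replaced by the object pixel, otherwise the base
#' pixel is kept unchanged.
#'
#' @param base,obj RGB images of identical dimensions.
#' @param obj_mask Logical `H x W` matrix matching both.
#' @return The composited RGB image.
#' @export
paste_object <- function(base, obj, obj_mask) {
  base <- rgb_image(base); obj <- rgb_image(obj)
  if (!identical(dim(base), dim(obj)) ||
      !all(dim(obj_mask) == dim(base)[1:2]))
    stop("base, object and mask dimensions must match", call. = FALSE)
  out <- base
  for (ch in 1:3) {
    b <- out[, , ch]; o <- obj[, , ch]
    b[obj_mask] <- o[obj_mask]
    out[, , ch] <- b
  }
  out
}

#' Gamma correction of an 8-bit image
#'
#' Remaps intensities as `round(255 * (v / 255) ^ gamma)`. Gamma below 1
#' brightens, above 1 darkens; 0 and 255 are fixed points and the map is
#' monotone non-decreasing for any fixed gamma.
#'
#' @param img An RGB image array.
#' @param gamma Positive exponent.
#' @return The corrected RGB image.
#' @export
gamma_correct <- function(img, gamma) {
  img <- rgb_image(img)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be a single positive number", call. = FALSE)
  out <- round(255 * (img / 255)^gamma)
  array(as.integer(pmin(255L, pmax(0L, out))), dim = dim(img))
}

#' Tight bounding box of a binary mask
#'
#' Returns the smallest axis-aligned box covering all `TRUE` pixels, in
#' 0-based half-open pixel coordinates (`x` = column, `y` = row from the
#' top), or `NULL` for an empty mask.
#'
#' @param mask Logical matrix.
#' @return Named numeric vector `c(xmin, ymin, xmax, ymax)` or `NULL`.
#' @export
bbox_from_mask <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  c(xmin = min(idx[, 2]) - 1, ymin = min(idx[, 1]) - 1,
    xmax = max(idx[, 2]),     ymax = max(idx[, 1]))
}

#' A plant source image for compositing
#'
#' Bundles a source photograph, its plant mask (see [plant_mask()]) and
#' the class of the plant it contains (0 = sugar beet, 1 = bindweed in
#' the default two-class setting).
#'
#' @param image RGB image array.
#' @param mask Logical matrix of the same height/width; must contain at
#'   least one `TRUE` pixel.
#' @param class_id Non-negative integer class id.
#' @param id Optional identifier carried into provenance records.
#' @return A list of class `"plant_source"`.
#' @export
plant_source <- function(image, mask, class_id, id = NULL) {
  image <- rgb_image(image)
  stopifnot(is.logical(mask), all(dim(mask) == dim(image)[1:2]))
  if (!any(mask)) stop("plant mask is empty", call. = FALSE)
  stopifnot(length(class_id) == 1L, class_id >= 0)
  structure(list(image = image, mask = mask,
                 class_id = as.integer(class_id), id = id),
            class = "plant_source")
}

#' Compositing parameters
#'
#' @param min_visible_frac Minimum fraction of the object's pre-transform
#'   mask area that must remain visible on the canvas after its transform;
#'   below this the transforms are resampled.
#' @param max_retries Bound on transform resampling attempts per pair.
#' @param gamma_grid Gamma values sampled for whole-composite brightness
#'   adjustment.
#' @return A parameter list.
#' @export
compose_params <- function(min_visible_frac = 0.25, max_retries = 20L,
                           gamma_grid = seq(0.5, 1.5, by = 0.2)) {
  stopifnot(min_visible_frac >= 0, min_visible_frac <= 1,
            max_retries >= 1, all(gamma_grid > 0))
  list(min_visible_frac = min_visible_frac,
       max_retries = as.integer(max_retries),
       gamma_grid = gamma_grid)
}

#' Compose one synthetic training image from a base and an object source
#'
#' The base source is transformed with a base transform (its own plant
#' mask transformed alongside, so the base plant stays labelled); the
#' object source is transformed with an object transform and pasted onto
#' the base through its transformed mask; finally a gamma drawn from the
#' gamma grid adjusts the brightness of the whole composite. If the
#' object's visible mask area after its transform falls below
#' `min_visible_frac` of its pre-transform area (objects pushed
#' off-canvas or shrunk away), transforms are resampled up to
#' `max_retries` times.
#'
#' @param base,obj [plant_source()] objects of identical image size.
#' @param params See [compose_params()].
#' @param seed Optional integer; when given, the composite is a pure
#'   function of `(base, obj, seed, params)`.
#' @return A list of class `"composite_record"` with elements `image`
#'   (gamma-corrected composite), `labels` (data frame `class_id, cx,
#'   cy, w, h`, darknet-normalized, base plant first), and `provenance`
#'   (source ids, both transform specs, gamma).
#' @export
compose_pair <- function(base, obj, params = compose_params(), seed = NULL) {
  stopifnot(inherits(base, "plant_source"), inherits(obj, "plant_source"))
  if (!identical(dim(base$image), dim(obj$image)))
    stop("base and object sources must share image dimensions", call. = FALSE)
  with_local_seed(seed, {
    h <- dim(base$image)[1]; w <- dim(base$image)[2]
    obj_area <- sum(obj$mask)
    done <- FALSE
    for (try in seq_len(params$max_retries)) {
      base_spec <- sample_base_transform()
      obj_spec <- sample_object_transform()
      tb <- apply_transform(base$image, base$mask, base_spec)
      if (!any(tb$mask)) next  # base plant zoomed/rotated off-canvas
      to <- apply_transform(obj$image, obj$mask, obj_spec)
      if (sum(to$mask) < params$min_visible_frac * obj_area) next
      done <- TRUE
      break
    }
    if (!done)
      stop(sprintf("no admissible transform pair for sources (%s, %s) in %d tries",
                   base$id %||% "base", obj$id %||% "object",
                   params$max_retries), call. = FALSE)
    composite <- paste_object(tb$image, to$image, to$mask)
    gamma <- sample(params$gamma_grid, 1L)
    composite <- gamma_correct(composite, gamma)
    boxes <- rbind(bbox_from_mask(tb$mask), bbox_from_mask(to$mask))
    labels <- data.frame(
      class_id = c(base$class_id, obj$class_id),
      cx = (boxes[, "xmin"] + boxes[, "xmax"]) / 2 / w,
      cy = (boxes[, "ymin"] + boxes[, "ymax"]) / 2 / h,
      w = (boxes[, "xmax"] - boxes[, "xmin"]) / w,
      h = (boxes[, "ymax"] - boxes[, "ymin"]) / h,
      row.names = NULL
    )
    structure(list(
      image = composite, labels = labels,
      provenance = list(base_id = base$id, object_id = obj$id,
                        base_spec = base_spec, object_spec = obj_spec,
                        gamma = gamma)
    ), class = "composite_record")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Schedule of composite pairs for a synthetic dataset
#'
#' Enumerates the pairs to composite: every (beet base, weed object)
#' combination once ("mixed"), every ordered (weed, weed) pair including
#' self-pairs ("weed_weed"), and `n_beet_beet` (beet, beet) pairs drawn
#' uniformly without replacement from the full ordered grid. With 51
#' beet and 26 weed sources and 269 beet-beet pairs this yields the
#' 1326 + 676 + 269 = 2271 composites of the reference configuration.
#'
#' @param n_beet,n_weed Numbers of source images per class.
#' @param n_beet_beet Number of beet-beet pairs to draw.
#' @param seed Seed for the beet-beet subsample.
#' @return Data frame with columns `kind`, `base_idx`, `obj_idx`.
#' @export
dataset_schedule <- function(n_beet, n_weed, n_beet_beet, seed = 1L) {
  stopifnot(n_beet >= 1, n_weed >= 1, n_beet_beet >= 0)
  if (n_beet_beet > n_beet^2)
    stop(sprintf("requested %d beet-beet pairs but only %d exist",
                 n_beet_beet, n_beet^2), call. = FALSE)
  mixed <- expand.grid(base_idx = seq_len(n_beet), obj_idx = seq_len(n_weed))
  weed <- expand.grid(base_idx = seq_len(n_weed), obj_idx = seq_len(n_weed))
  bb_all <- expand.grid(base_idx = seq_len(n_beet), obj_idx = seq_len(n_beet))
  bb <- with_local_seed(seed,
    bb_all[sample.int(nrow(bb_all), n_beet_beet), , drop = FALSE])
  out <- rbind(
    cbind(kind = "mixed", mixed),
    cbind(kind = "weed_weed", weed),
    cbind(kind = "beet_beet", bb)
  )
  rownames(out) <- NULL
  out
}

#' Generate a labelled synthetic dataset on disk
#'
#' Runs [compose_pair()] over the full [dataset_schedule()], writing one
#' PNG image and one darknet-style label file per composite plus a
#' `manifest.csv` listing paths, labels, and provenance. Mixed pairs use
#' the beet source as base and the weed as pasted object; weed-weed and
#' beet-beet pairs follow the schedule's (base, object) order. The whole
#' run is a pure function of (sources, counts, seed).
#'
#' @param beet_sources,weed_sources Lists of [plant_source()] objects
#'   (class ids 0 and 1 respectively, by convention).
#' @param n_beet_beet Number of beet-beet composites.
#' @param seed Master seed; every per-composite transform draw derives
#'   from it.
#' @param out_dir Output directory (created if missing).
#' @param params See [compose_params()].
#' @return The manifest data frame, invisibly.
#' @export
generate_dataset <- function(beet_sources, weed_sources, n_beet_beet,
                             seed, out_dir, params = compose_params()) {
  stopifnot(length(beet_sources) >= 1, length(weed_sources) >= 1)
  sched <- dataset_schedule(length(beet_sources), length(weed_sources),
                            n_beet_beet, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  item_seeds <- with_local_seed(seed,
    sample.int(.Machine$integer.max, nrow(sched)))
  rows <- vector("list", nrow(sched))
  for (i in seq_len(nrow(sched))) {
    kind <- sched$kind[i]
    base <- switch(kind,
      mixed = beet_sources[[sched$base_idx[i]]],
      weed_weed = weed_sources[[sched$base_idx[i]]],
      beet_beet = beet_sources[[sched$base_idx[i]]])
    obj <- switch(kind,
      mixed = weed_sources[[sched$obj_idx[i]]],
      weed_weed = weed_sources[[sched$obj_idx[i]]],
      beet_beet = beet_sources[[sched$obj_idx[i]]])
    rec <- compose_pair(base, obj, params = params, seed = item_seeds[i])
    stem <- sprintf("img_%05d", i)
    img_path <- file.path(out_dir, paste0(stem, ".png"))
    lbl_path <- file.path(out_dir, paste0(stem, ".txt"))
    write_image(rec$image, img_path)
    write_labels(rec$labels, lbl_path)
    pv <- rec$provenance
    rows[[i]] <- data.frame(
      image = img_path, labels = lbl_path, kind = kind,
      base_idx = sched$base_idx[i], obj_idx = sched$obj_idx[i],
      base_rotation = pv$base_spec$rotation_deg,
      base_zoom = pv$base_spec$zoom, base_flip = pv$base_spec$flip,
      obj_rotation = pv$object_spec$rotation_deg,
      obj_zoom = pv$object_spec$zoom,
      obj_dx = pv$object_spec$shift_px[1],
      obj_dy = pv$object_spec$shift_px[2],
      obj_flip = pv$object_spec$flip,
      gamma = pv$gamma, item_seed = item_seeds[i]
    )
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
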