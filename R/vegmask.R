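#' Validate an 8-bit RGB image array
#'
#' The universal pixel container of the package is a plain `H x W x 3`
#' numeric array with integer values in `[0, 255]`, channels ordered
#' red, green, blue, row-major with the origin at the top-left corner.
#'
#' @param pixels An `H x W x 3` array of integers in `[0, 255]`.
#' @return The validated array, invisibly unchanged.
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("an RGB image must be an H x W x 3 array", call. = FALSE)
  if (anyNA(pixels))
    stop("RGB image contains missing values", call. = FALSE)
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255)
    stop("RGB values must lie in [0, 255]", call. = FALSE)
  if (any(pixels != floor(pixels)))
    stop("RGB values must be whole numbers (8-bit intensities)", call. = FALSE)
  pixels
}

#' Normalize RGB channels to chromaticity coordinates
#'
#' Divides each channel by the per-pixel channel sum `R + G + B`, giving
#' the chromaticity triple (r, g, b) with `r + g + b = 1` wherever the sum
#' is nonzero. Pure black pixels (sum zero) are mapped to `(0, 0, 0)` by
#' convention, so shadows never register as vegetation downstream.
#'
#' @param img An RGB image (see [rgb_image()]).
#' @return A list with matrices `r`, `g`, `b`, each `H x W` in `[0, 1]`.
#' @export
#' @examples
#' px <- array(c(50, 150, 50), dim = c(1, 1, 3))
#' normalize_rgb(px)$g  # 0.6
normalize_rgb <- function(img) {
  img <- rgb_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  chan <- function(ch) matrix(img[, , ch], h, w)
  s <- chan(1) + chan(2) + chan(3)
  nz <- s > 0
  out <- lapply(1:3, function(ch) {
    m <- matrix(0, h, w)
    m[nz] <- chan(ch)[nz] / s[nz]
    m
  })
  names(out) <- c("r", "g", "b")
  out
}

#' Excess-green (ExG) vegetation index
#'
#' Computes `ExG = 2g - r - b` on the chromaticity-normalized channels.
#' Since `r + g + b = 1` at every non-black pixel, this equals `3g - 1`
#' there; values lie in `[-1, 2]`. Green vegetation scores high, soil and
#' gray material near zero.
#'
#' @inheritParams normalize_rgb
#' @return An `H x W` numeric matrix of ExG values.
#' @export
#' @examples
#' excess_green(array(c(0, 255, 0), dim = c(1, 1, 3)))  # 2
excess_green <- function(img) {
  n <- normalize_rgb(img)
  2 * n$g - n$r - n$b
}

#' Otsu's threshold over a histogram of real values
#'
#' Classic between-class-variance maximization, applied to an arbitrary
#' real-valued sample by linearly rescaling it onto the 8-bit range,
#' histogramming into `nbins` equal-width bins, exhaustively scanning all
#' bin splits, and mapping the best split boundary back to the original
#' scale. Ties on the between-class variance are broken toward the
#' lowest split, so the returned threshold always attains the maximum.
#'
#' @param values Numeric vector (or matrix) with at least two distinct
#'   values.
#' @param nbins Number of histogram bins (default 256, the 8-bit
#'   convention).
#' @return A single threshold on the scale of `values`, strictly between
#'   the sample minimum and maximum.
#' @export
otsu_threshold <- function(values, nbins = 256L) {
  v <- as.numeric(values)
  v <- v[!is.na(v)]
  if (length(v) < 2L) stop("need at least two values", call. = FALSE)
  lo <- min(v); hi <- max(v)
  if (hi <= lo)
    stop("degenerate histogram: all values identical", call. = FALSE)
  nbins <- as.integer(nbins)
  if (nbins < 2L) stop("nbins must be >= 2", call. = FALSE)

  # rescale to [0, nbins - 1] and bin; bin centres index the splits
  scaled <- (v - lo) / (hi - lo) * (nbins - 1L)
  idx <- pmin(nbins - 1L, floor(scaled))
  counts <- tabulate(idx + 1L, nbins = nbins)
  p <- counts / sum(counts)
  levels <- 0:(nbins - 1L)

  omega <- cumsum(p)                 # class-0 mass for split after bin t
  mu <- cumsum(p * levels)
  mu_t <- mu[nbins]
  # between-class variance for every split t = 0 .. nbins-2
  t_idx <- 1:(nbins - 1L)
  w0 <- omega[t_idx]
  num <- (mu_t * w0 - mu[t_idx])^2
  den <- w0 * (1 - w0)
  sigma_b <- ifelse(den > 0, num / den, 0)
  t_star <- levels[which.max(sigma_b)]  # split: bins <= t_star vs above

  # place the threshold midway between the closest observed values on
  # either side of the winning bin boundary, so strictly-greater
  # comparison realizes exactly the optimal histogram split
  left_max <- max(v[idx <= t_star])
  right_min <- min(v[idx > t_star])
  (left_max + right_min) / 2
}

#' Binary plant mask from an RGB image
#'
#' Computes the ExG map, thresholds it with [otsu_threshold()], and marks
#' as plant every pixel whose ExG value is strictly greater than the
#' threshold (ties go to background). Optionally keeps only the largest
#' 4-connected component of the mask, for sources known to contain a
#' single plant.
#'
#' @inheritParams normalize_rgb
#' @param keep_largest If `TRUE`, retain only the largest connected
#'   component (requires the EBImage package).
#' @return An `H x W` logical matrix, `TRUE` on plant pixels.
#' @export
plant_mask <- function(img, keep_largest = FALSE) {
  exg <- excess_green(img)
  thr <- otsu_threshold(exg)
  mask <- exg > thr
  if (keep_largest && any(mask)) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("keep_largest = TRUE requires the EBImage package", call. = FALSE)
    lab <- EBImage::bwlabel(t(mask) * 1)  # EBImage is x-major
    lab <- t(EBImage::imageData(lab))
    tab <- tabulate(lab[lab > 0])
    mask <- lab == which.max(tab)
  }
  mask
}
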