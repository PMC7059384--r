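# internal helpers shared across modules

# Evaluate expr under a temporary RNG seed, restoring the caller's
# RNG state afterwards so seeded module calls do not perturb each other.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# round half away from zero (commercial rounding); base round() is
# half-to-even, which would make the documented pixel conversions
# platform-visible special cases
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

# Bilinear sampling of matrix `m` (H x W) at real coordinates
# (xs, ys) given as H x W matrices in 1-based pixel-centre units.
# Out-of-canvas contributions are zero (black fill).
sample_bilinear <- function(m, xs, ys) {
  h <- nrow(m); w <- ncol(m)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  gather <- function(yy, xx) {
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    val <- matrix(0, nrow(xs), ncol(xs))
    val[ok] <- m[cbind(yy[ok], xx[ok])]
    val
  }
  v00 <- gather(y0,     x0)
  v01 <- gather(y0,     x0 + 1)
  v10 <- gather(y0 + 1, x0)
  v11 <- gather(y0 + 1, x0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# Nearest-neighbour sampling of a logical matrix; outside -> FALSE
sample_nearest <- function(m, xs, ys) {
  h <- nrow(m); w <- ncol(m)
  xr <- round(xs); yr <- round(ys)
  ok <- yr >= 1 & yr <= h & xr >= 1 & xr <= w
  val <- matrix(FALSE, nrow(xs), ncol(xs))
  val[ok] <- m[cbind(yr[ok], xr[ok])]
  val
}

# upscale a coarse matrix to (h, w) by bilinear interpolation of its
# grid (used by the fixture generator for low-frequency soil texture)
upscale_bilinear <- function(coarse, h, w) {
  ch <- nrow(coarse); cw <- ncol(coarse)
  ys <- matrix(seq(1, ch, length.out = h), h, w)
  xs <- matrix(seq(1, cw, length.out = w), h, w, byrow = TRUE)
  sample_bilinear(coarse, xs, ys)
}
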