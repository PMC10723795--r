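#' Rolling-ball background estimation and subtraction
#'
#' Estimates the slowly varying background of a fluorescence image as the
#' grayscale morphological opening with a ball-shaped (spherical-cap height)
#' structuring element of the given radius -- the classic rolling-ball
#' algorithm. Structures narrower than the ball diameter are preserved by the
#' subtraction; anything the ball can roll under is treated as background.
#' For large radii the image is processed on a block-minimum downsampled grid
#' and the background is interpolated back, as high-content plugins do.
#'
#' @param image Numeric matrix of intensities.
#' @param radius Ball radius in pixels (>= 1).
#' @param shrink Integer downsampling factor, or `"auto"` (downsample so the
#'   effective radius is about 16 px).
#' @param smooth Estimate the background on a 3x3-mean-filtered copy
#'   (default `TRUE`). Without it, the min-type ball operations latch onto
#'   the lowest noise excursions and systematically underestimate the
#'   background on photon-noisy images; the smoothed copy is used only for
#'   the estimate, never for the subtraction.
#' @return For `rolling_ball_background`, the background estimate (same
#'   dimensions, everywhere `<= image` after clamping). For
#'   `subtract_background`, `image - background`, everywhere `>= 0`.
#' @export
rolling_ball_background <- function(image, radius, shrink = "auto",
                                    smooth = TRUE) {
  if (!is.matrix(image) || !is.numeric(image)) stopf("`image` must be a numeric matrix")
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) || radius < 1)
    stopf("`radius` must be a single value >= 1")
  storage.mode(image) <- "double"
  if (identical(shrink, "auto")) shrink <- max(1L, as.integer(ceiling(radius / 16)))
  shrink <- as.integer(shrink)

  est <- if (smooth) mean_filter3(image) else image
  if (shrink > 1L) {
    small <- block_reduce_min(est, shrink)
    bg_small <- ball_opening(small, radius / shrink)
    bg <- upsample_bilinear(bg_small, dim(image), shrink)
  } else {
    bg <- ball_opening(est, radius)
  }
  pmin(bg, image)
}

#' @rdname rolling_ball_background
#' @export
subtract_background <- function(image, radius, shrink = "auto",
                                smooth = TRUE) {
  out <- image - rolling_ball_background(image, radius, shrink, smooth)
  out[out < 0] <- 0
  out
}

# 3x3 mean filter with border replication.
mean_filter3 <- function(image) {
  n <- nrow(image); m <- ncol(image)
  ri <- pmin(pmax(0:(n + 1L), 1L), n)
  ci <- pmin(pmax(0:(m + 1L), 1L), m)
  pad <- image[ri, ci, drop = FALSE]
  acc <- matrix(0, n, m)
  for (dy in 0:2) for (dx in 0:2)
    acc <- acc + pad[(1L + dy):(n + dy), (1L + dx):(m + dx)]
  acc / 9
}

# Grayscale opening with a ball (hemisphere-height) structuring element:
# erosion E(x) = min_o [ f(x + o) - z(o) ], dilation D(x) = max_o [ E(x + o) + z(o) ],
# z(o) = sqrt(r^2 - |o|^2). Edge handling replicates border pixels.
ball_opening <- function(image, radius) {
  off <- ball_offsets(radius)
  er <- shift_reduce(image, off, "erode")
  shift_reduce(er, off, "dilate")
}

ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  d2 <- g$dy^2 + g$dx^2
  keep <- d2 <= radius^2
  list(dy = g$dy[keep], dx = g$dx[keep],
       z = sqrt(pmax(radius^2 - d2[keep], 0)))
}

# Vectorised min/max over structuring-element offsets using a border-replicated
# padded copy; each offset is one slice + pmin/pmax over the whole image.
shift_reduce <- function(image, off, op = c("erode", "dilate")) {
  op <- match.arg(op)
  n <- nrow(image); m <- ncol(image)
  r <- max(abs(c(off$dy, off$dx)))
  ri <- pmin(pmax(seq_len(n + 2L * r) - r, 1L), n)
  ci <- pmin(pmax(seq_len(m + 2L * r) - r, 1L), m)
  pad <- image[ri, ci, drop = FALSE]
  acc <- NULL
  for (k in seq_along(off$dy)) {
    sl <- pad[(r + 1L + off$dy[k]):(r + n + off$dy[k]),
              (r + 1L + off$dx[k]):(r + m + off$dx[k]), drop = FALSE]
    v <- if (op == "erode") sl - off$z[k] else sl + off$z[k]
    acc <- if (is.null(acc)) v else if (op == "erode") pmin(acc, v) else pmax(acc, v)
  }
  acc
}

# Minimum over shrink x shrink blocks (conservative for background estimation);
# ragged edges are padded by border replication.
block_reduce_min <- function(image, s) {
  n <- nrow(image); m <- ncol(image)
  nb <- as.integer(ceiling(n / s)); mb <- as.integer(ceiling(m / s))
  x <- image[pmin(seq_len(nb * s), n), pmin(seq_len(mb * s), m), drop = FALSE]
  rmin <- matrix(apply(matrix(x, nrow = s), 2L, min), nrow = nb)   # nb x (mb*s)
  cmin <- matrix(apply(matrix(t(rmin), nrow = s), 2L, min), nrow = mb)
  t(cmin)                                                          # nb x mb
}

# Bilinear upsample of the block grid back to the original dimensions; block
# centers are at ( (i-0.5)*s + 0.5 ) in original coordinates.
upsample_bilinear <- function(small, dims, s) {
  n <- dims[1L]; m <- dims[2L]
  nb <- nrow(small); mb <- ncol(small)
  pos_r <- ((seq_len(n)) - (0.5 + (s - 1) / 2)) / s + 0.5
  pos_c <- ((seq_len(m)) - (0.5 + (s - 1) / 2)) / s + 0.5
  r0 <- pmin(pmax(floor(pos_r), 1L), nb); r1 <- pmin(r0 + 1L, nb)
  c0 <- pmin(pmax(floor(pos_c), 1L), mb); c1 <- pmin(c0 + 1L, mb)
  wr <- pmin(pmax(pos_r - r0, 0), 1); wc <- pmin(pmax(pos_c - c0, 0), 1)
  a <- small[r0, c0, drop = FALSE]; b <- small[r0, c1, drop = FALSE]
  d <- small[r1, c0, drop = FALSE]; e <- small[r1, c1, drop = FALSE]
  WR <- matrix(wr, n, m); WC <- matrix(wc, n, m, byrow = TRUE)
  (1 - WR) * ((1 - WC) * a + WC * b) + WR * ((1 - WC) * d + WC * e)
}
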