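## Canny edge detection.
## Hand-written because no installed R package exposes one; EBImage supplies
## only the morphology and labelling around it. Operates on plain matrices
## indexed [row, col].

shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

reflect_pad <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(k) + 1L), seq_len(nr), nr - seq_len(k))
  ci <- c(rev(seq_len(k) + 1L), seq_len(nc), nc - seq_len(k))
  m[ri, ci]
}

#' 2D convolution with reflective boundary
#'
#' @param m matrix.
#' @param kernel odd-sized convolution kernel.
#' @return Matrix of the same shape.
#' @keywords internal
conv2_reflect <- function(m, kernel) {
  k <- (max(dim(kernel)) - 1L) %/% 2L
  p <- reflect_pad(m, k)
  out <- EBImage::filter2(p, kernel, boundary = "circular")
  out[(k + 1):(k + nrow(m)), (k + 1):(k + ncol(m))]
}

#' Normalized Gaussian kernel
#'
#' @param size odd kernel side length (pixels).
#' @param sigma standard deviation (pixels).
#' @return `size` x `size` matrix summing to 1.
#' @keywords internal
gaussian_kernel <- function(size, sigma) {
  stopifnot(size %% 2 == 1, size >= 3)
  r <- (size - 1) / 2
  x <- -r:r
  g <- exp(-outer(x^2, x^2, "+") / (2 * sigma^2))
  g / sum(g)
}

#' Canny edge detector
#'
#' Classic four-stage Canny: Gaussian smoothing, Sobel gradients,
#' non-maximum suppression along the quantized gradient direction, and
#' hysteresis thresholding (weak-edge components are kept only when they
#' contain a strong pixel). Hysteresis thresholds are fractions of the
#' maximum gradient magnitude found in the image (the usual convention):
#' Gaussian smoothing scales all gradients down by about `1/sigma`, so
#' relative thresholds stay meaningful at any smoothing scale, which
#' absolute grey-level thresholds would not.
#'
#' @param img numeric matrix `[row, col]`.
#' @param sigma Gaussian smoothing scale in pixels; `0` skips smoothing
#'   (useful when the caller has already low-pass filtered).
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   gradient magnitude, in `[0, 1]`. Ignored when `auto = TRUE`.
#' @param auto if `TRUE`, derive the high threshold by Otsu's split of the
#'   surviving gradient magnitudes and set `low = 0.4 * high`; adapts to
#'   the contrast actually present, which suits faint membrane edges.
#' @return Logical matrix, `TRUE` on edge pixels.
#' @export
canny_edges <- function(img, sigma = 2, low = 0.1, high = 0.2, auto = FALSE) {
  stopifnot(is.matrix(img), nrow(img) > 1, ncol(img) > 1)
  if (sigma > 0) {
    size <- 2L * ceiling(3 * sigma) + 1L
    img <- conv2_reflect(img, gaussian_kernel(size, sigma))
  }
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE) / 4
  gx <- conv2_reflect(img, sx)
  gy <- conv2_reflect(img, t(sx))
  g <- sqrt(gx^2 + gy^2)
  # FFT-based convolution leaves ~1e-13 ripple on flat regions; clamp it so
  # a constant image stays edge-free
  g[g < 1e-8 * (diff(range(img)) + 1)] <- 0

  # quantize gradient direction to 4 sectors and suppress non-maxima
  ang <- atan2(gy, gx) %% pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  # sector 0: gradient along columns (0, 1); 1: diagonal (1, 1);
  # 2: along rows (1, 0); 3: anti-diagonal (1, -1)
  drs <- c(0L, 1L, 1L, 1L)
  dcs <- c(1L, 1L, 0L, -1L)
  nms <- matrix(FALSE, nrow(g), ncol(g))
  for (s in 0:3) {
    n1 <- shift_mat(g, drs[s + 1], dcs[s + 1])
    n2 <- shift_mat(g, -drs[s + 1], -dcs[s + 1])
    nms <- nms | (sector == s & g >= n1 & g >= n2)
  }
  nms <- nms & g > 0

  gmax <- max(g)
  if (gmax == 0) return(matrix(FALSE, nrow(g), ncol(g)))
  if (auto) {
    vals <- g[nms & g > 0]
    if (!length(vals)) return(matrix(FALSE, nrow(g), ncol(g)))
    high <- otsu_scalar(vals, range = c(0, max(vals)))
    low <- 0.4 * high
  } else {
    high <- high * gmax
    low <- low * gmax
  }
  strong <- nms & g >= high
  weak <- nms & g >= low
  if (!any(strong)) return(matrix(FALSE, nrow(g), ncol(g)))
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[strong])
  weak & (lab %in% keep[keep > 0])
}

#' Label super-pixels from Canny edges
#'
#' Detects edges and labels each 8-connected component of the remaining
#' non-edge pixels as a distinct super-pixel. Edge pixels carry label 0;
#' super-pixel labels are positive integers. The edge set is first
#' thickened by a 1-px dilation (`thicken`): a one-pixel 8-connected curve
#' does not separate an 8-connected complement, so unthickened edges would
#' leak regions into each other through diagonal gaps.
#'
#' @param img numeric matrix `[row, col]`.
#' @param thicken dilation radius (px) applied to the edge set before
#'   labelling; 0 disables.
#' @inheritParams canny_edges
#' @return Integer matrix of super-pixel labels (0 = edge).
#' @export
canny_superpixels <- function(img, sigma = 2, low = 0.1, high = 0.2,
                              auto = FALSE, thicken = 1) {
  edges <- canny_edges(img, sigma = sigma, low = low, high = high, auto = auto)
  if (thicken > 0 && any(edges))
    edges <- EBImage::dilate(edges, EBImage::makeBrush(2L * thicken + 1L,
                                                       "disc")) > 0
  lab <- EBImage::bwlabel(!edges)
  storage.mode(lab) <- "integer"
  lab
}
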