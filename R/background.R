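#' Parameters for background (resin) segmentation
#'
#' The resin in which cells are embedded images brighter than the cells and
#' fairly uniformly, so a slice separates into background and cells by
#' intensity. These parameters steer that stage.
#'
#' @param canny_sigma Gaussian scale (px) of the Canny detector used to form
#'   super-pixels.
#' @param low_frac,high_frac Canny hysteresis thresholds as fractions of
#'   the maximum gradient magnitude in the slice.
#' @param min_size_frac minimum background-component area, as a fraction of
#'   the slice area; smaller components are removed.
#' @param max_hole_frac holes in the background mask smaller than this
#'   fraction of slice area are filled (larger holes are cells).
#' @param close_radius disc radius (px) of the final binary closing.
#' @param min_contrast minimum separation (grey levels) between the mean
#'   intensities of the two Otsu classes; below it the slice has no
#'   intensity contrast to exploit (an Otsu split of a unimodal histogram
#'   would fabricate one) and is classified wholesale by `uniform_bright`.
#' @param uniform_bright mean grey level above which a contrast-free slice
#'   counts as all resin rather than all cell; intensities are assumed
#'   contrast-adjusted 8-bit with bright resin, so 150 sits between the
#'   typical cell and resin levels.
#' @return A named list of parameters.
#' @export
background_params <- function(canny_sigma = 2, low_frac = 0.1, high_frac = 0.2,
                              min_size_frac = 5e-4, max_hole_frac = 1e-3,
                              close_radius = 5, min_contrast = 30,
                              uniform_bright = 150) {
  list(canny_sigma = canny_sigma, low_frac = low_frac, high_frac = high_frac,
       min_size_frac = min_size_frac, max_hole_frac = max_hole_frac,
       close_radius = close_radius, min_contrast = min_contrast,
       uniform_bright = uniform_bright)
}

# Otsu on a vector of values: exhaustive maximization of between-class
# variance over a fixed histogram.
otsu_scalar <- function(values, range = c(0, 255), levels = 256L) {
  # bins centred on the representable grey levels, so integer data shifted
  # by a constant moves between bins without re-quantization
  step <- (range[2] - range[1]) / (levels - 1L)
  breaks <- seq(range[1] - step / 2, range[2] + step / 2, length.out = levels + 1L)
  h <- tabulate(findInterval(values, breaks, all.inside = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  if (all(between == 0)) stop("degenerate histogram: cannot split a constant slice")
  # the maximizing index i splits after bin i: the bright class starts at
  # the next representable level, so the threshold sits half a step above
  mids[which.max(between)] + step / 2
}

#' Otsu's threshold for a slice
#'
#' The grey level that maximizes the between-class variance of the slice
#' histogram (256 levels over the 8-bit range). Deterministic.
#'
#' @param slice numeric matrix of intensities in `[0, 255]`.
#' @return Scalar threshold; pixels `>=` threshold belong to the brighter
#'   class.
#' @export
otsu_threshold <- function(slice) {
  stopifnot(length(slice) > 0)
  otsu_scalar(as.vector(slice), range = c(0, 255))
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

remove_small <- function(mask, min_size) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  mask & matrix(lab %in% keep, nrow(mask))
}

fill_small_holes <- function(mask, max_hole) {
  # a hole is a non-mask component not touching the image border
  inv <- !mask
  lab <- EBImage::bwlabel(inv)
  if (max(lab) == 0) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0])
  fill <- setdiff(which(sizes < max_hole), border)
  if (length(fill)) mask <- mask | matrix(lab %in% fill, nrow(mask))
  mask
}

#' Segment the resin background of one slice
#'
#' Combines Otsu intensity thresholding with Canny-edge super-pixels: a
#' super-pixel is classified background when its median intensity is at or
#' above the Otsu threshold (the median resists the dark organelle speckle
#' inside cells). Edge pixels inherit the class of their own intensity. The
#' union is cleaned morphologically: components smaller than `min_size_frac`
#' of the slice are dropped, holes smaller than `max_hole_frac` filled, and
#' the mask closed with a disc.
#'
#' When the slice has no exploitable intensity contrast (class-mean
#' separation below `min_contrast`, e.g. an all-cell field) an all-`FALSE`
#' mask is returned with a warning: absence of background is a documented
#' limitation of the cell-identification stage.
#'
#' @param slice numeric matrix of intensities in `[0, 255]`.
#' @param params a [background_params()] list.
#' @return Logical matrix, `TRUE` on background (resin) pixels.
#' @export
segment_background_slice <- function(slice, params = background_params()) {
  stopifnot(is.matrix(slice), length(slice) > 0)
  thr <- tryCatch(otsu_threshold(slice), error = function(e) NA_real_)
  degenerate <- is.na(thr)
  if (!degenerate) {
    lo <- slice[slice < thr]; hi <- slice[slice >= thr]
    if (!length(lo) || !length(hi) ||
        (mean(hi) - mean(lo)) < params$min_contrast) degenerate <- TRUE
  }
  if (degenerate) {
    if (mean(slice) >= params$uniform_bright)
      return(matrix(TRUE, nrow(slice), ncol(slice)))
    warning("no background found: intensity contrast below min_contrast")
    return(matrix(FALSE, nrow(slice), ncol(slice)))
  }

  sp <- canny_superpixels(slice, sigma = params$canny_sigma,
                          low = params$low_frac, high = params$high_frac)
  mask <- matrix(FALSE, nrow(slice), ncol(slice))
  if (max(sp) > 0) {
    med <- vapply(split(as.vector(slice)[sp > 0], sp[sp > 0]),
                  stats::median, numeric(1))
    bg_labels <- as.integer(names(med))[med >= thr]
    mask <- matrix(sp %in% bg_labels, nrow(slice))
  }
  mask[sp == 0] <- slice[sp == 0] >= thr

  min_size <- params$min_size_frac * length(slice)
  max_hole <- params$max_hole_frac * length(slice)
  mask <- remove_small(mask, min_size)
  mask <- fill_small_holes(mask, max_hole)
  mask <- EBImage::closing(mask, disc_brush(params$close_radius)) > 0
  mask <- remove_small(mask, min_size)
  # resin is the embedding medium: every true background region reaches the
  # field border, so bright islands enclosed inside cells (e.g. a bright
  # nucleoplasm) are not background
  lab <- EBImage::bwlabel(mask)
  if (max(lab) > 0) {
    keep <- setdiff(border_labels(lab), 0L)
    mask <- mask & matrix(lab %in% keep, nrow(mask))
  }
  mask
}

#' Segment background over selected slices of a volume
#'
#' Applies [segment_background_slice()] independently to each requested
#' slice; the analysis typically samples the stack sparsely (e.g. every 20th
#' slice) since cells span many slices.
#'
#' @param vol a [volume_stack()].
#' @param slice_indices integer vector of slice indices (1-based).
#' @param params a [background_params()] list.
#' @return Named list of logical masks, one per requested slice, names the
#'   slice indices, in the requested order.
#' @export
segment_background_volume <- function(vol, slice_indices,
                                      params = background_params()) {
  stopifnot(inherits(vol, "volume_stack"))
  nz <- dim(vol$data)[1]
  if (any(slice_indices < 1 | slice_indices > nz))
    stop("slice indices out of bounds [1, ", nz, "]")
  masks <- purrr::map(slice_indices, function(z) {
    tryCatch(segment_background_slice(vol$data[z, , ], params),
             error = function(e) stop("slice ", z, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
  stats::setNames(masks, slice_indices)
}
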