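#' Parameters for nuclear-envelope segmentation
#'
#' @param gauss_size odd Gaussian kernel side (px) for the low-pass
#'   pre-filter; default 7.
#' @param gauss_sigma Gaussian standard deviation (px); default 2.
#' @param canny_sigma smoothing scale of the Canny stage applied after the
#'   low-pass (default 0: the explicit low-pass already smooths).
#' @param edge_link_base base linking distance (px): edge pixels within the
#'   (adaptive) linking distance are fused into one edge, bridging the gaps
#'   that intensity variation leaves in the envelope. The effective distance
#'   is `edge_link_base * max(1, canny_sigma / 2)`, growing with the Canny
#'   scale since coarser detection displaces edges further.
#' @param min_region_frac minimum super-pixel area as a fraction of slice
#'   area (default 0.001).
#' @param max_hole_frac holes smaller than this fraction of slice area are
#'   filled (default 0.01).
#' @param close_radius disc radius (px) of the final closing that smooths
#'   the jagged envelope outline.
#' @param canny_low,canny_high explicit hysteresis thresholds (intensity
#'   units/px); `NULL` (default) derives them automatically by Otsu on the
#'   gradient magnitude.
#' @param overlap_frac minimum fraction of a candidate component's area
#'   that must overlap the propagated prior mask (default 0.3). A pure
#'   any-overlap rule cannot terminate at the nucleus pole: one slice past
#'   it the candidate is the whole cell interior, which always overlaps the
#'   prior, while its overlap fraction collapses. Set to 0 for any-overlap.
#' @return A named list of parameters.
#' @export
ne_params <- function(gauss_size = 7, gauss_sigma = 2, canny_sigma = 0,
                      edge_link_base = 5, min_region_frac = 1e-3,
                      max_hole_frac = 1e-2, close_radius = 5,
                      canny_low = NULL, canny_high = NULL,
                      overlap_frac = 0.3) {
  stopifnot(gauss_size %% 2 == 1, gauss_size >= 3, edge_link_base >= 1)
  list(gauss_size = gauss_size, gauss_sigma = gauss_sigma,
       canny_sigma = canny_sigma, edge_link_base = edge_link_base,
       min_region_frac = min_region_frac, max_hole_frac = max_hole_frac,
       close_radius = close_radius, canny_low = canny_low,
       canny_high = canny_high, overlap_frac = overlap_frac)
}

#' Low-pass filter a slice
#'
#' 2D Gaussian convolution (reflective boundaries) that removes the
#' high-frequency noise of the electron micrographs before edge detection.
#'
#' @param slice numeric matrix.
#' @param params an [ne_params()] list (uses `gauss_size`, `gauss_sigma`).
#' @return Filtered matrix, same shape and intensity range.
#' @export
lowpass <- function(slice, params = ne_params()) {
  conv2_reflect(slice, gaussian_kernel(params$gauss_size, params$gauss_sigma))
}

#' Thickened envelope edge mask
#'
#' Canny edges of the filtered slice, then every pixel within the adaptive
#' linking distance of an edge becomes edge (computed from the distance map
#' of the edge set), so disjoint envelope segments fuse into a single
#' closed edge.
#'
#' @param filtered matrix from [lowpass()].
#' @param params an [ne_params()] list.
#' @return Logical matrix of the thickened edge set.
#' @export
ne_edge_mask <- function(filtered, params = ne_params()) {
  auto <- is.null(params$canny_low) || is.null(params$canny_high)
  edges <- canny_edges(filtered, sigma = params$canny_sigma,
                       low = params$canny_low %||% 0,
                       high = params$canny_high %||% 0, auto = auto)
  if (!any(edges)) return(edges)
  d <- EBImage::distmap(1 - edges)
  matrix(as.numeric(d) <= ne_link_dist(params), nrow(edges))
}

# adaptive linking distance: grows with the scale of the edge detector
ne_link_dist <- function(params) {
  params$edge_link_base *
    max(1, max(params$canny_sigma, params$gauss_sigma) / 2)
}

component_stats <- function(lab) {
  n <- max(lab)
  if (n == 0) return(tibble::tibble(label = integer(), area = integer(),
                                    row = numeric(), col = numeric()))
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  tibble::tibble(
    label = seq_len(n),
    area = tabulate(l, n),
    row = as.numeric(tapply(idx[, 1], l, mean)[as.character(seq_len(n))]),
    col = as.numeric(tapply(idx[, 2], l, mean)[as.character(seq_len(n))]))
}

border_labels <- function(lab) {
  unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
}

#' Segment the nucleus on one slice
#'
#' The filtered slice is decomposed into super-pixels (connected components
#' of non-edge pixels under the thickened Canny edge set). Components
#' touching the image border are removed, as are components below
#' `min_region_frac`. With no prior, the nucleus is the large, central
#' component (score `area / (1 + distance to ROI centre)`); with a prior
#' mask (propagated from the neighbouring slice) every component overlapping
#' the prior is kept and all others discarded. The selection is finished by
#' filling small holes and closing the jagged outline.
#'
#' @param slice numeric matrix (raw intensities; the low-pass is applied
#'   internally).
#' @param params an [ne_params()] list.
#' @param prior optional logical mask from the neighbouring slice.
#' @param center `(row, col)` used for central selection; defaults to the
#'   slice centre.
#' @return Logical nucleus mask (possibly empty, with a warning, when the
#'   slice holds no nucleus), with attribute `provenance` one of
#'   `"seed"`/`"propagated"`.
#' @export
segment_nucleus_slice <- function(slice, params = ne_params(), prior = NULL,
                                  center = NULL) {
  if (is.null(center)) center <- (dim(slice) + 1) / 2
  filt <- lowpass(slice, params)
  edges <- ne_edge_mask(filt, params)
  lab <- EBImage::bwlabel(!edges)
  drop <- border_labels(lab)
  min_area <- params$min_region_frac * length(slice)

  stats <- component_stats(lab)
  stats <- dplyr::filter(stats, !(.data$label %in% drop), .data$area >= min_area)

  empty <- matrix(FALSE, nrow(slice), ncol(slice))
  if (!nrow(stats)) {
    warning("no nucleus candidate on this slice")
    return(structure(empty, provenance = if (is.null(prior)) "seed" else "propagated"))
  }

  if (is.null(prior)) {
    # distance from the ROI centre to the component itself (0 when the
    # component contains the centre): a centroid distance would favour the
    # cytoplasm annulus around the nucleus, whose centroid is also central
    idx <- which(lab > 0, arr.ind = TRUE)
    pd <- sqrt((idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2)
    mind <- tapply(pd, lab[lab > 0], min)
    dist0 <- as.numeric(mind[as.character(stats$label)])
    score <- stats$area / (1 + dist0)^2
    keep <- stats$label[which.max(score)]
  } else {
    ov <- vapply(stats$label, function(l) sum(prior[lab == l]), numeric(1))
    need <- pmax(1, params$overlap_frac * stats$area)
    keep <- stats$label[ov >= need]
    if (!length(keep)) {
      warning("no component overlaps the propagated prior: nucleus ended")
      return(structure(empty, provenance = "propagated"))
    }
  }

  mask <- matrix(lab %in% keep, nrow(slice))
  # the thickened edge consumed a band of width ne_link_dist around the
  # nucleoplasm; dilating by the same disc restores the boundary to the
  # detected envelope edge
  mask <- EBImage::dilate(mask, disc_brush(ne_link_dist(params))) > 0
  mask <- fill_small_holes(mask, params$max_hole_frac * length(slice))
  mask <- EBImage::closing(mask, disc_brush(params$close_radius)) > 0
  # the border rule survives closing
  lab2 <- EBImage::bwlabel(mask)
  bad <- setdiff(border_labels(lab2), 0L)
  if (length(bad)) mask <- mask & !matrix(lab2 %in% bad, nrow(mask))
  structure(mask, provenance = if (is.null(prior)) "seed" else "propagated")
}

#' Segment the nucleus through an ROI volume
#'
#' Starts at the seed slice — by default the central slice, which for a
#' centred cell is near the equator of the nucleus, where its cross-section
#' is largest and easiest to find — and propagates the segmentation
#' bidirectionally: each segmented mask becomes the prior of the next slice
#' outward, and candidate components survive only if they overlap that
#' prior. Propagation in a direction stops at the first empty mask (the
#' nucleus pole).
#'
#' @param roi a [volume_stack()] cropped around one cell.
#' @param params an [ne_params()] list.
#' @param seed_slice seed slice index; default the central slice. Override
#'   for partial cells whose nucleus equator sits off-centre.
#' @param center in-plane `(row, col)` the seed-slice selection treats as
#'   the expected nucleus position; default the ROI centre (the stated
#'   assumption is a cell-centred ROI). Override for off-centre cells.
#' @return A [label_volume()] with nucleus voxels coded 2, all else 0.
#' @export
segment_nucleus_volume <- function(roi, params = ne_params(),
                                   seed_slice = NULL, center = NULL) {
  stopifnot(inherits(roi, "volume_stack"))
  nz <- dim(roi$data)[1]
  if (is.null(seed_slice)) seed_slice <- (nz + 1L) %/% 2L
  stopifnot(seed_slice >= 1, seed_slice <= nz)

  seed <- segment_nucleus_slice(roi$data[seed_slice, , ], params,
                                center = center)
  if (!any(seed))
    stop("no nucleus found at seed slice ", seed_slice,
         "; move the seed (seed_slice) towards the nucleus equator")

  labs <- array(0L, dim(roi$data))
  labs[seed_slice, , ] <- seed * 2L
  prior <- seed
  if (seed_slice < nz) for (z in (seed_slice + 1L):nz) {
    m <- suppressWarnings(
      segment_nucleus_slice(roi$data[z, , ], params, prior = prior))
    if (!any(m)) break
    labs[z, , ] <- m * 2L
    prior <- m
  }
  prior <- seed
  if (seed_slice > 1) for (z in (seed_slice - 1L):1L) {
    m <- suppressWarnings(
      segment_nucleus_slice(roi$data[z, , ], params, prior = prior))
    if (!any(m)) break
    labs[z, , ] <- m * 2L
    prior <- m
  }
  label_volume(labs, class_codes = c(background = 0L, nucleus = 2L))
}
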