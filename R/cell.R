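#' Parameters for plasma-membrane segmentation
#'
#' @param se_radius disc radius (px) of the large structuring element used
#'   to open the raw watershed region; removes straight artefactual wedges
#'   that watershed lines leave, along with natural protrusions (added back
#'   by [merge_protrusions()]). Default 30 px at the 10 nm/px acquisition
#'   scale; scale with expected cell radius.
#' @param surround_frac minimum fraction of a candidate region's outer
#'   boundary that must touch background or the cell core for the region to
#'   merge (default 0.8, "surrounded by background").
#' @param max_merge_frac a candidate larger than this fraction of the core
#'   area is never merged (default 0.5): protuberances are small relative to
#'   the cell, and without the cap a neighbouring cell ringed by resin would
#'   satisfy the surround test and swallow the whole instance.
#' @param merge_max_halfwidth maximum half-width (px) of a mergeable
#'   candidate: a candidate containing a disc of this radius is a cell-body
#'   mass (e.g. the polar cross-section of a touching neighbour), not a
#'   membrane appendage, and is never merged. Default `se_radius / 3`.
#' @return A named list of parameters.
#' @export
cell_params <- function(se_radius = 30, surround_frac = 0.8,
                        max_merge_frac = 0.5,
                        merge_max_halfwidth = NULL) {
  stopifnot(se_radius >= 1, surround_frac >= 0, surround_frac <= 1)
  if (is.null(merge_max_halfwidth))
    merge_max_halfwidth <- max(2, round(se_radius / 3))
  list(se_radius = se_radius, surround_frac = surround_frac,
       max_merge_frac = max_merge_frac,
       merge_max_halfwidth = merge_max_halfwidth)
}

#' Watershed the distance map into cell regions
#'
#' The distance map of a cell-centred ROI has one tall hill at the central
#' cell and lower hills at its neighbours; flooding the (negated) altitude
#' map assigns each non-background pixel to the catchment basin of one
#' hill, separating touching cells along the valleys between them.
#' Background pixels (altitude 0) are excluded (label 0). Flooding in
#' EBImage is deterministic, so identical maps give identical labels.
#'
#' @param dmap distance map from [distance_map()].
#' @return Integer matrix of basin labels, 0 on background.
#' @export
watershed_cells <- function(dmap) {
  stopifnot(is.matrix(dmap))
  if (!any(dmap > 0)) return(matrix(0L, nrow(dmap), ncol(dmap)))
  ws <- EBImage::watershed(dmap)
  out <- matrix(as.integer(ws), nrow(dmap))
  out[dmap <= 0] <- 0L
  out
}

#' Select the central watershed region
#'
#' Returns the basin containing the anchor (canonically the nucleus
#' centroid). If the anchor falls on background or a ridge, falls back to
#' the basin maximizing `area / (1 + distance of its centroid to the
#' anchor)` — large and central wins.
#'
#' @param labels integer basin matrix from [watershed_cells()].
#' @param anchor `(row, col)`; defaults to the image centre.
#' @return Logical mask of the selected basin.
#' @export
select_central_region <- function(labels, anchor = NULL) {
  if (is.null(anchor)) anchor <- (dim(labels) + 1) / 2
  anchor <- round(anchor)
  if (max(labels) == 0) stop("no cell found in ROI: watershed produced no regions")
  if (anchor[1] < 1 || anchor[1] > nrow(labels) ||
      anchor[2] < 1 || anchor[2] > ncol(labels))
    stop("anchor outside the ROI")
  l <- labels[anchor[1], anchor[2]]
  if (l == 0) {
    stats <- component_stats(labels)
    stats <- dplyr::filter(stats, .data$area > 0)
    score <- stats$area / (1 + sqrt((stats$row - anchor[1])^2 +
                                    (stats$col - anchor[2])^2))
    l <- stats$label[which.max(score)]
  }
  labels == l
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) return(mask)
  lab == which.max(tabulate(lab[lab > 0]))
}

#' Open the raw cell region with a large structuring element
#'
#' Binary opening with a disc removes protruding artefactual regions that
#' the watershed attaches to the cell, leaving a fairly round core; only
#' the largest component is kept. Opening is anti-extensive: the result is
#' always a subset of the input.
#'
#' @param raw logical mask from [select_central_region()].
#' @param se_radius disc radius in pixels.
#' @return Logical core mask.
#' @export
smooth_open <- function(raw, se_radius = 30) {
  stopifnot(se_radius >= 1)
  core <- EBImage::opening(raw, disc_brush(se_radius)) > 0
  if (!any(core))
    stop("opening erased the cell region: use a smaller se_radius")
  largest_component(core)
}

dilate1 <- function(mask) EBImage::dilate(mask, disc_brush(1)) > 0

#' Merge membrane protrusions back onto the cell core
#'
#' Candidate regions are the connected components of non-background pixels
#' outside the core. A candidate merges when (a) it touches the core
#' (8-connectivity), (b) at least `surround_frac` of its outer boundary
#' touches background or core — i.e. it is a protuberance of this cell, not
#' shared territory with a neighbour —, (c) it is small relative to the
#' core (`max_merge_frac`), and (d) it is thin: it contains no disc of
#' radius `merge_max_halfwidth`, which separates membrane appendages from
#' the compact cross-section of a neighbouring cell. Merging repeats until
#' no candidate qualifies, so chains of protrusion fragments attach.
#' Regions sandwiched between the cell and a neighbour with little
#' intervening background fail (b) and are left out: the segmentation stays
#' a cautious lower bound of the cell.
#'
#' @param core logical core mask from [smooth_open()].
#' @param bg logical background mask of the same slice.
#' @param surround_frac,max_merge_frac,merge_max_halfwidth see
#'   [cell_params()].
#' @return Logical final cell mask (single connected component containing
#'   the core).
#' @export
merge_protrusions <- function(core, bg, surround_frac = 0.8,
                              max_merge_frac = 0.5,
                              merge_max_halfwidth = 10) {
  stopifnot(any(core))
  core_area0 <- sum(core)
  repeat {
    cand <- EBImage::bwlabel(!bg & !core)
    if (max(cand) == 0) break
    core_d <- dilate1(core)
    touching <- setdiff(unique(cand[core_d & cand > 0]), 0L)
    merged_any <- FALSE
    for (l in touching) {
      reg <- cand == l
      if (sum(reg) > max_merge_frac * core_area0) next
      if (any(EBImage::erode(reg, disc_brush(merge_max_halfwidth)) > 0)) next
      boundary <- dilate1(reg) & !reg
      frac <- sum(boundary & (bg | core)) / sum(boundary)
      if (frac >= surround_frac) {
        core <- core | reg
        merged_any <- TRUE
      }
    }
    if (!merged_any) break
  }
  largest_component(core)
}

segment_cell_slice <- function(slice_bg, anchor, params) {
  dmap <- distance_map(slice_bg)
  ws <- watershed_cells(dmap)
  raw <- select_central_region(ws, anchor)
  # polar cross-sections can be smaller than the structuring element;
  # halve it until the opening keeps something
  se <- params$se_radius
  core <- NULL
  while (is.null(core) && se >= 2) {
    core <- tryCatch(smooth_open(raw, se), error = function(e) NULL)
    if (is.null(core)) se <- se %/% 2
  }
  if (is.null(core)) stop("opening erased the cell region at every scale")
  merge_protrusions(core, slice_bg, params$surround_frac,
                    params$max_merge_frac, params$merge_max_halfwidth)
}

#' Instance-segment the central cell through an ROI volume
#'
#' Sweeps outward from the seed slice (the slice with the largest
#' segmented nucleus cross-section, or the ROI middle without a nucleus),
#' applying the per-slice pipeline: distance map of the background,
#' watershed, central-region selection (anchored at the slice's nucleus
#' centroid when available, else the previously accepted cell centroid,
#' else the ROI centre), opening with a large structuring element, and
#' protrusion merging. A slice's mask is accepted only if it overlaps the
#' previously accepted mask (fraction `continuity_frac` of the smaller of
#' the two): past the cell's poles the watershed would otherwise latch onto
#' a neighbour, since some basin always exists wherever background remains.
#' Slices whose segmentation fails leave the cell absent there (not
#' fatal). The result assembles classes background 0, cell cytoplasm 1,
#' nucleus 2 (overriding cell: classes are exclusive) and neighbour 3
#' (non-background voxels not claimed by the cell).
#'
#' @param roi a [volume_stack()] cropped around one cell.
#' @param bg_masks list of logical background masks, one per ROI slice (in
#'   slice order).
#' @param nucleus optional [label_volume()] from
#'   [segment_nucleus_volume()].
#' @param params a [cell_params()] list.
#' @param continuity_frac minimum overlap between consecutive accepted
#'   cell masks, as a fraction of the smaller mask (default 0.3).
#' @return A [label_volume()] over the ROI.
#' @export
segment_cell_volume <- function(roi, bg_masks, nucleus = NULL,
                                params = cell_params(),
                                continuity_frac = 0.3) {
  stopifnot(inherits(roi, "volume_stack"))
  nz <- dim(roi$data)[1]
  stopifnot(length(bg_masks) == nz)
  if (!any(vapply(bg_masks, any, logical(1))))
    stop("no background present on any ROI slice: the plasma-membrane ",
         "segmentation requires a visible resin background to form the ",
         "distance map (known limitation); only the nuclear envelope can ",
         "be segmented in such data")

  nuc_area <- if (!is.null(nucleus)) {
    vapply(seq_len(nz), function(z) sum(nucleus$labels[z, , ] == 2L),
           numeric(1))
  } else rep(0, nz)
  seed_z <- if (any(nuc_area > 0)) which.max(nuc_area) else (nz + 1L) %/% 2L

  cell_masks <- vector("list", nz)
  do_slice <- function(z, prev_mask) {
    bg <- bg_masks[[z]]
    if (!any(bg) || all(bg)) return(NULL)
    nuc_slice <- if (!is.null(nucleus)) nucleus$labels[z, , ] == 2L else NULL
    anchor <- NULL
    if (!is.null(nuc_slice) && any(nuc_slice)) {
      idx <- which(nuc_slice, arr.ind = TRUE)
      anchor <- c(mean(idx[, 1]), mean(idx[, 2]))
    } else if (!is.null(prev_mask)) {
      idx <- which(prev_mask, arr.ind = TRUE)
      anchor <- c(mean(idx[, 1]), mean(idx[, 2]))
    }
    cell <- tryCatch(segment_cell_slice(bg, anchor, params),
                     error = function(e) {
                       message("slice ", z, ": cell absent (",
                               conditionMessage(e), ")")
                       NULL
                     })
    if (is.null(cell)) return(NULL)
    if (!is.null(prev_mask)) {
      ov <- sum(cell & prev_mask)
      if (ov < continuity_frac * min(sum(cell), sum(prev_mask))) {
        message("slice ", z, ": region lost 3D continuity with the cell; ",
                "cell ended")
        return(NULL)
      }
    }
    cell
  }

  cell_masks[[seed_z]] <- do_slice(seed_z, NULL)
  prev <- cell_masks[[seed_z]]
  if (seed_z < nz) for (z in (seed_z + 1L):nz) {
    m <- do_slice(z, prev)
    if (is.null(m)) break
    cell_masks[[z]] <- m
    prev <- m
  }
  prev <- cell_masks[[seed_z]]
  if (seed_z > 1L) for (z in (seed_z - 1L):1L) {
    m <- do_slice(z, prev)
    if (is.null(m)) break
    cell_masks[[z]] <- m
    prev <- m
  }

  labs <- array(0L, dim(roi$data))
  for (z in seq_len(nz)) {
    bg <- bg_masks[[z]]
    sl <- matrix(0L, dim(labs)[2], dim(labs)[3])
    if (!is.null(cell_masks[[z]])) sl[cell_masks[[z]]] <- 1L
    sl[!bg & sl == 0L] <- 3L
    if (!is.null(nucleus)) sl[nucleus$labels[z, , ] == 2L] <- 2L
    labs[z, , ] <- sl
  }
  label_volume(labs)
}
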