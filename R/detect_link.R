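#' Distance ("altitude") map of a slice
#'
#' Exact Euclidean distance from each non-background pixel to the nearest
#' background pixel; zero on background. Each cell becomes a "hill" whose
#' height grows with cell size, so hilltops rank cells by size.
#'
#' @param mask logical background mask (`TRUE` = resin), as produced by
#'   [segment_background_slice()].
#' @return Numeric matrix of distances in pixels.
#' @export
distance_map <- function(mask) {
  stopifnot(is.matrix(mask), length(mask) > 0)
  if (!any(mask)) {
    stop("mask contains no background: the distance map is undefined; ",
         "a visible resin background is required for cell detection")
  }
  cells <- !mask
  d <- EBImage::distmap(cells * 1)
  matrix(as.numeric(d), nrow(mask))
}

zero_disc <- function(m, center, radius) {
  nr <- nrow(m); nc <- ncol(m)
  rs <- max(1, center[1] - radius):min(nr, center[1] + radius)
  cs <- max(1, center[2] - radius):min(nc, center[2] + radius)
  sub_r <- outer((rs - center[1])^2, (cs - center[2])^2, "+") <= radius^2
  m[rs, cs][sub_r] <- 0
  m
}

#' Detect and rank cells on one slice
#'
#' Greedy peak picking on the distance map: the global maximum is the
#' largest cell (rank 1); everything within `suppression_radius` of it is
#' then suppressed, since a single cell produces a ridge of near-equal peaks,
#' and the process repeats until `n_cells` are found or the map is
#' exhausted. Ties in peak height are broken by (row, col) order, so the
#' result is deterministic.
#'
#' @param dmap distance map matrix from [distance_map()].
#' @param n_cells maximum number of cells to detect (default 20).
#' @param suppression_radius radius (px) suppressed around each accepted
#'   peak; should be of the order of a cell radius.
#' @param slice_index slice position recorded in the output.
#' @return A tibble with one row per detection: `slice_index`, `rank`,
#'   `peak_row`, `peak_col`, `peak_height`, `centroid_row`, `centroid_col`
#'   (centroid of the suppressed support region). Peak heights are
#'   non-increasing in rank.
#' @export
detect_cells_slice <- function(dmap, n_cells = 20, suppression_radius = 300,
                               slice_index = NA_integer_) {
  stopifnot(n_cells >= 1, suppression_radius > 0)
  m <- dmap
  out <- vector("list", n_cells)
  k <- 0L
  while (k < n_cells) {
    peak_h <- max(m)
    if (peak_h <= 0) break
    hits <- which(m == peak_h, arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    pk <- hits[1, ]
    # support centroid: positive-altitude pixels inside the suppression disc
    rs <- max(1, pk[1] - suppression_radius):min(nrow(m), pk[1] + suppression_radius)
    cs <- max(1, pk[2] - suppression_radius):min(ncol(m), pk[2] + suppression_radius)
    sub <- m[rs, cs]
    in_disc <- outer((rs - pk[1])^2, (cs - pk[2])^2, "+") <= suppression_radius^2
    supp <- which(sub > 0 & in_disc, arr.ind = TRUE)
    k <- k + 1L
    out[[k]] <- tibble::tibble(
      slice_index = slice_index, rank = k,
      peak_row = unname(pk[1]), peak_col = unname(pk[2]),
      peak_height = peak_h,
      centroid_row = mean(rs[supp[, 1]]),
      centroid_col = mean(cs[supp[, 2]]))
    m <- zero_disc(m, pk, suppression_radius)
  }
  if (k == 0L) {
    return(tibble::tibble(slice_index = integer(), rank = integer(),
                          peak_row = integer(), peak_col = integer(),
                          peak_height = numeric(), centroid_row = numeric(),
                          centroid_col = numeric()))
  }
  dplyr::bind_rows(out[seq_len(k)])
}

#' Detect cells across sampled slices of a stack
#'
#' Segments the background of each sampled slice and runs
#' [detect_cells_slice()] on its distance map.
#'
#' @param vol a [volume_stack()].
#' @param slice_indices slices to analyse (e.g. every 20th).
#' @param n_cells,suppression_radius see [detect_cells_slice()].
#' @param bg_params a [background_params()] list.
#' @return A tibble of detections over all analysed slices.
#' @export
detect_cells_volume <- function(vol, slice_indices, n_cells = 20,
                                suppression_radius = 300,
                                bg_params = background_params()) {
  masks <- segment_background_volume(vol, slice_indices, bg_params)
  purrr::map2_dfr(masks, slice_indices, function(mask, z) {
    if (!any(mask)) return(tibble::tibble())
    detect_cells_slice(distance_map(mask), n_cells = n_cells,
                       suppression_radius = suppression_radius,
                       slice_index = z)
  })
}

#' Link per-slice detections into cell tracks
#'
#' Detections on consecutive analysed slices are chained when they are
#' mutual nearest neighbours in the image plane and closer than
#' `max_lateral_shift`. Per-slice rank is never used for identity: rank
#' orders cells by size within a slice, and the same physical cell changes
#' rank from slice to slice. Unmatched detections open new tracks.
#'
#' @param detections tibble from [detect_cells_volume()] (or a bound set of
#'   [detect_cells_slice()] outputs with `slice_index` filled in).
#' @param max_lateral_shift maximum in-plane peak displacement (px) between
#'   consecutive analysed slices for two detections to be the same cell.
#' @return The detections tibble with a `track_id` column added.
#' @export
link_detections <- function(detections, max_lateral_shift = 500) {
  if (!nrow(detections)) return(dplyr::mutate(detections, track_id = integer()))
  det <- dplyr::arrange(detections, .data$slice_index, .data$rank)
  det$track_id <- NA_integer_
  slices <- sort(unique(det$slice_index))
  next_id <- 1L
  first <- which(det$slice_index == slices[1])
  det$track_id[first] <- seq_along(first)
  next_id <- length(first) + 1L
  for (i in seq_along(slices)[-1]) {
    prev <- which(det$slice_index == slices[i - 1])
    cur <- which(det$slice_index == slices[i])
    if (length(prev) && length(cur)) {
      dmat <- outer(det$peak_row[prev], det$peak_row[cur], "-")^2 +
        outer(det$peak_col[prev], det$peak_col[cur], "-")^2
      dmat <- sqrt(dmat)
      nn_of_cur <- apply(dmat, 2, which.min)   # best previous for each current
      nn_of_prev <- apply(dmat, 1, which.min)  # best current for each previous
      for (j in seq_along(cur)) {
        p <- nn_of_cur[j]
        if (nn_of_prev[p] == j && dmat[p, j] <= max_lateral_shift) {
          det$track_id[cur[j]] <- det$track_id[prev[p]]
        }
      }
    }
    open <- cur[is.na(det$track_id[cur])]
    if (length(open)) {
      det$track_id[open] <- next_id + seq_along(open) - 1L
      next_id <- next_id + length(open)
    }
  }
  det
}

#' Summarise linked detections into one row per track
#'
#' The 3D centroid of a track is the mean of its member peaks weighted by
#' peak height, so slices where the cell is largest (near its equator)
#' dominate.
#'
#' @param linked tibble from [link_detections()].
#' @return A tibble with one row per track: `track_id`, `n_detections`,
#'   `first_slice`, `last_slice`, `centroid_slice`, `centroid_row`,
#'   `centroid_col`, `max_peak_height`, and a `detections` list-column.
#' @export
summarise_tracks <- function(linked) {
  linked |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n_detections = dplyr::n(),
      first_slice = min(.data$slice_index),
      last_slice = max(.data$slice_index),
      centroid_slice = stats::weighted.mean(.data$slice_index, .data$peak_height),
      centroid_row = stats::weighted.mean(.data$peak_row, .data$peak_height),
      centroid_col = stats::weighted.mean(.data$peak_col, .data$peak_height),
      max_peak_height = max(.data$peak_height),
      detections = list(dplyr::pick(dplyr::everything())),
      .groups = "drop")
}

#' Select tracks for further processing
#'
#' Tracks whose in-plane centroid lies within `edge_margin` of a lateral
#' volume face are discarded: their ROI could not be centred on the cell and
#' may contain two partial cells. Tracks near the axial (top/bottom) faces
#' are kept but flagged `partial` — such cells are still centred laterally
#' and can be segmented over the slices where they appear.
#'
#' @param tracks tibble from [summarise_tracks()].
#' @param parent_shape integer length-3 `(depth, height, width)` of the
#'   source volume.
#' @param edge_margin lateral margin in pixels (default 500).
#' @param axial_margin slices from top/bottom within which a track is
#'   flagged partial (default half the ROI depth, 150).
#' @return The tracks tibble with logical `kept`, `partial` and character
#'   `discard_reason` columns added.
#' @export
select_tracks <- function(tracks, parent_shape, edge_margin = 500,
                          axial_margin = 150) {
  stopifnot(edge_margin >= 0)
  tracks |>
    dplyr::mutate(
      dist_edge = pmin(.data$centroid_row - 1,
                       parent_shape[2] - .data$centroid_row,
                       .data$centroid_col - 1,
                       parent_shape[3] - .data$centroid_col),
      kept = .data$dist_edge >= edge_margin,
      partial = .data$kept &
        (pmin(.data$centroid_slice - 1,
              parent_shape[1] - .data$centroid_slice) < axial_margin),
      discard_reason = dplyr::if_else(
        .data$kept, NA_character_,
        sprintf("centroid %.0f px from lateral edge (< margin %g)",
                .data$dist_edge, edge_margin)))
}

#' Build ROI crop windows from selected tracks
#'
#' One window of `roi_size` per kept track, centred on the track's 3D
#' centroid. For tracks near the top or bottom of the stack the depth
#' placement is shifted (not clipped) so the realized window keeps full
#' depth whenever the stack allows, while the cell stays laterally centred.
#'
#' @param tracks tibble from [select_tracks()] (discarded tracks are
#'   ignored).
#' @param parent_shape integer length-3 of the source volume.
#' @param roi_size integer length-3 `(depth, height, width)`, default
#'   `c(300, 2000, 2000)`.
#' @return A tibble with `track_id` and a `window` list-column of
#'   [roi_window()] objects.
#' @export
tracks_to_windows <- function(tracks, parent_shape,
                              roi_size = c(300, 2000, 2000)) {
  stopifnot(all(roi_size >= 1))
  kept <- if ("kept" %in% names(tracks)) dplyr::filter(tracks, .data$kept) else tracks
  d <- roi_size[1]
  windows <- purrr::pmap(
    list(kept$centroid_slice, kept$centroid_row, kept$centroid_col),
    function(cz, cy, cx) {
      cz <- round(cz)
      if (parent_shape[1] >= d) {
        # shift the depth window fully inside the stack
        cz <- min(max(cz, d %/% 2 + 1), parent_shape[1] - d + d %/% 2 + 1)
      }
      roi_window(center = c(cz, round(cy), round(cx)), size = roi_size)
    })
  tibble::tibble(track_id = kept$track_id, window = windows)
}
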