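#' Full-pipeline configuration
#'
#' Collects every stage's parameters. The only choices a user must make for
#' a new stack are the number of cells to look for per slice and which
#' slices to analyse; everything else has scale-documented defaults.
#'
#' @param n_cells cells detected per analysed slice (default 20).
#' @param slice_step analyse every `slice_step`-th slice (default 20).
#' @param suppression_radius peak suppression radius (px); of the order of
#'   a cell radius.
#' @param max_lateral_shift linking tolerance (px) between analysed slices.
#' @param edge_margin lateral discard margin (px, default 500).
#' @param axial_margin axial partial-cell flag margin (slices).
#' @param roi_size ROI `(depth, height, width)` (default 300 x 2000 x 2000).
#' @param background a [background_params()] list.
#' @param nucleus an [ne_params()] list.
#' @param cell a [cell_params()] list.
#' @param evaluate logical: score against ground truth when provided.
#' @param seed RNG seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_cells = 20, slice_step = 20,
                            suppression_radius = 300,
                            max_lateral_shift = 500, edge_margin = 500,
                            axial_margin = 150,
                            roi_size = c(300, 2000, 2000),
                            background = background_params(),
                            nucleus = ne_params(), cell = cell_params(),
                            evaluate = TRUE, seed = 1L) {
  stopifnot(n_cells >= 1, slice_step >= 1, suppression_radius > 0,
            edge_margin >= 0, all(roi_size >= 1))
  structure(list(n_cells = n_cells, slice_step = slice_step,
                 suppression_radius = suppression_radius,
                 max_lateral_shift = max_lateral_shift,
                 edge_margin = edge_margin, axial_margin = axial_margin,
                 roi_size = as.integer(roi_size), background = background,
                 nucleus = nucleus, cell = cell, evaluate = evaluate,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the nested
#' `background:`, `nucleus:` and `cell:` blocks mirror
#' [background_params()], [ne_params()] and [cell_params()].
#'
#' @param path YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("background", "nucleus", "cell"))]
  if (!is.null(y$background)) args$background <- do.call(background_params, y$background)
  if (!is.null(y$nucleus)) args$nucleus <- do.call(ne_params, y$nucleus)
  if (!is.null(y$cell)) args$cell <- do.call(cell_params, y$cell)
  do.call(pipeline_config, args)
}

stage_done <- function(path) file.exists(path)

#' Run the whole segmentation pipeline
#'
#' detect -> link -> select -> crop -> per-ROI nucleus -> per-ROI cell ->
#' (optional) evaluate. Every artifact lands under `work_dir` in a
#' per-stage layout (`detect/`, `roi_01/`, ...) and is listed in the JSON
#' manifest together with parameters and per-stage wall time. With
#' `resume = TRUE`, stages whose outputs already exist are skipped, so a
#' failed ROI can be recomputed without repeating the rest. A failure in
#' one ROI is recorded in the manifest and later ROIs still run.
#'
#' @param vol a [volume_stack()], or a path readable by [read_stack()].
#' @param work_dir output directory.
#' @param config a [pipeline_config()].
#' @param truth optional phantom result from [generate_phantom()]; enables
#'   per-ROI evaluation against voxel-exact truth.
#' @param resume skip stages whose outputs exist.
#' @return The run manifest (a list), invisibly written to
#'   `work_dir/manifest.json`.
#' @export
run_pipeline <- function(vol, work_dir, config = pipeline_config(),
                         truth = NULL, resume = FALSE) {
  if (is.character(vol)) vol <- read_stack(vol)
  stopifnot(inherits(vol, "volume_stack"), inherits(config, "pipeline_config"))
  dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(parameters = unclass(config), files = character(0),
                   stages = list(), rois = list())
  tick <- function() proc.time()[["elapsed"]]

  # ---- detection, linking, selection -------------------------------------
  detect_dir <- file.path(work_dir, "detect")
  dir.create(detect_dir, showWarnings = FALSE)
  tracks_csv <- file.path(detect_dir, "tracks.csv")
  det_csv <- file.path(detect_dir, "detections.csv")
  t0 <- tick()
  if (resume && stage_done(tracks_csv)) {
    tracks <- tibble::as_tibble(utils::read.csv(tracks_csv))
    linked <- tibble::as_tibble(utils::read.csv(det_csv))
  } else {
    nz <- dim(vol)[1]
    slices <- seq(1L, nz, by = config$slice_step)
    dets <- detect_cells_volume(vol, slices, n_cells = config$n_cells,
                                suppression_radius = config$suppression_radius,
                                bg_params = config$background)
    linked <- link_detections(dets, max_lateral_shift = config$max_lateral_shift)
    tracks <- summarise_tracks(linked) |>
      select_tracks(dim(vol), edge_margin = config$edge_margin,
                    axial_margin = config$axial_margin)
    utils::write.csv(linked, det_csv, row.names = FALSE)
    utils::write.csv(dplyr::select(tracks, -"detections"), tracks_csv,
                     row.names = FALSE)
  }
  manifest$stages$detect <- list(seconds = tick() - t0,
                                 n_tracks = nrow(tracks),
                                 n_kept = sum(tracks$kept))
  manifest$files <- c(manifest$files, det_csv, tracks_csv)
  if (!any(tracks$kept)) {
    message("no tracks survive selection (edge_margin = ",
            config$edge_margin, "): nothing to segment")
    manifest$rois <- list()
    jsonlite::write_json(manifest, file.path(work_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    return(invisible(manifest))
  }

  windows <- tracks_to_windows(tracks, dim(vol), roi_size = config$roi_size)

  # ---- per-ROI segmentation ----------------------------------------------
  for (i in seq_len(nrow(windows))) {
    tid <- windows$track_id[i]
    roi_dir <- file.path(work_dir, sprintf("roi_%02d", tid))
    entry <- list(track_id = tid, dir = roi_dir)
    t0 <- tick()
    res <- tryCatch({
      dir.create(roi_dir, showWarnings = FALSE)
      cropped <- crop_roi(vol, windows$window[[i]])
      roi <- cropped$roi
      entry$offset <- cropped$window$offset
      entry$size <- cropped$window$realized_size
      nuc_dir <- file.path(roi_dir, "nucleus")
      cell_dir <- file.path(roi_dir, "cell")
      if (!(resume && stage_done(file.path(cell_dir, "z0000.tiff")))) {
        # seed at the track centroid (ROI coordinates): the window centre is
        # depth-shifted for cropping and the ROI may be clipped laterally,
        # so neither the nucleus equator nor the cell centre need sit at
        # the ROI middle
        trk <- tracks[tracks$track_id == tid, ]
        ctr_roi <- round(c(trk$centroid_slice, trk$centroid_row,
                           trk$centroid_col)) - cropped$window$offset + 1L
        ctr_roi <- as.integer(pmin(pmax(ctr_roi, 1L), dim(roi)))
        nucleus <- segment_nucleus_volume(roi, config$nucleus,
                                          seed_slice = ctr_roi[1],
                                          center = ctr_roi[2:3])
        write_label_stack(nucleus, nuc_dir)
        bg <- purrr::map(seq_len(dim(roi)[1]), function(z)
          suppressWarnings(segment_background_slice(roi$data[z, , ],
                                                    config$background)))
        labels <- segment_cell_volume(roi, bg, nucleus = nucleus,
                                      params = config$cell)
        write_label_stack(labels, cell_dir)
      } else {
        labels <- read_label_stack(cell_dir)
      }
      entry$nucleus_dir <- nuc_dir
      entry$cell_dir <- cell_dir
      if (config$evaluate && !is.null(truth)) {
        ctr <- windows$window[[i]]$center
        cid <- truth$truth$instances[ctr[1], ctr[2], ctr[3]]
        if (cid == 0) {
          d2 <- (truth$truth$cells$center_row - ctr[2])^2 +
            (truth$truth$cells$center_col - ctr[3])^2
          cid <- truth$truth$cells$id[which.min(d2)]
        }
        roi_truth <- phantom_roi_truth(truth, windows$window[[i]], cid)
        rep <- evaluate_scenarios(labels, roi_truth)
        utils::write.csv(rep, file.path(roi_dir, "evaluation.csv"),
                         row.names = FALSE)
        entry$evaluation <- tibble::as_tibble(rep)
      }
      entry
    }, error = function(e) {
      entry$error <- conditionMessage(e)
      entry
    })
    res$seconds <- tick() - t0
    manifest$rois[[sprintf("roi_%02d", tid)]] <- res
  }
  manifest$files <- c(manifest$files,
                      list.files(work_dir, recursive = TRUE, full.names = TRUE))
  manifest$files <- sort(unique(manifest$files))
  jsonlite::write_json(manifest, file.path(work_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

tint <- function(gray, mask, rgb_w) {
  # blend a translucent colour over masked pixels of a [0,1] gray image
  out <- array(rep(gray, 3), c(dim(gray), 3))
  for (ch in 1:3) {
    p <- out[, , ch]
    p[mask] <- 0.55 * p[mask] + 0.45 * rgb_w[ch]
    out[, , ch] <- p
  }
  out
}

#' Export per-slice overlay images
#'
#' Writes PNG composites of selected slices: cells tinted red, nuclei
#' green over the grayscale micrograph. When `truth` is given, a second
#' comparison image per slice renders false negatives white, false
#' positives black, and correct voxels (TP and TN) grey, for the scenario
#' of the cell including its nucleus.
#'
#' @param vol a [volume_stack()].
#' @param labels a [label_volume()] of the same shape.
#' @param slices slice indices to export.
#' @param dir output directory.
#' @param truth optional [label_volume()] ground truth.
#' @return Invisibly, the files written.
#' @export
overlay_export <- function(vol, labels, slices, dir, truth = NULL) {
  stopifnot(identical(dim(vol), dim(labels)))
  nz <- dim(vol)[1]
  if (any(slices < 1 | slices > nz)) stop("slice index out of range")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (z in slices) {
    gray <- vol$data[z, , ] / 255
    lab <- labels$labels[z, , ]
    comp <- tint(gray, lab == 1L, c(1, 0.2, 0.2))
    green <- tint(gray, lab == 2L, c(0.2, 1, 0.2))
    sel <- array(rep(lab == 2L, 3), dim(comp))
    comp[sel] <- green[sel]
    f <- file.path(dir, sprintf("overlay_z%04d.png", z - 1L))
    png::writePNG(comp, f)
    files <- c(files, f)
    if (!is.null(truth)) {
      pm <- lab == 1L | lab == 2L
      tm <- truth$labels[z, , ] == 1L | truth$labels[z, , ] == 2L
      cmp <- matrix(0.5, nrow(gray), ncol(gray))
      cmp[!pm & tm] <- 1    # FN white
      cmp[pm & !tm] <- 0    # FP black
      f2 <- file.path(dir, sprintf("compare_z%04d.png", z - 1L))
      png::writePNG(cmp, f2)
      files <- c(files, f2)
    }
  }
  invisible(files)
}

#' Plot detected tracks over the stack footprint
#'
#' In-plane map of linked detections: one line/point set per track, grey
#' for discarded tracks, with the lateral discard margin drawn.
#'
#' @param linked detections tibble from [link_detections()].
#' @param tracks tibble from [select_tracks()].
#' @param parent_shape volume dimensions.
#' @param edge_margin margin drawn on the map.
#' @return A ggplot object.
#' @export
plot_tracks <- function(linked, tracks, parent_shape, edge_margin = 500) {
  df <- dplyr::left_join(linked,
                         dplyr::select(tracks, "track_id", "kept"),
                         by = "track_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$peak_col, y = .data$peak_row,
                                   group = .data$track_id,
                                   colour = factor(.data$track_id),
                                   alpha = .data$kept)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(ggplot2::aes(size = .data$peak_height)) +
    ggplot2::annotate("rect", xmin = edge_margin,
                      xmax = parent_shape[3] - edge_margin,
                      ymin = edge_margin,
                      ymax = parent_shape[2] - edge_margin,
                      fill = NA, colour = "grey40", linetype = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25),
                                guide = "none") +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "column (px)", y = "row (px)", size = "peak height",
                  title = "Linked cell tracks (in-plane)") +
    ggplot2::theme_minimal()
}
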