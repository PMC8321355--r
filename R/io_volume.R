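#' Volumetric image stack
#'
#' Constructs a `volume_stack`, the package's container for a 3D grayscale
#' image volume as acquired by serial block-face SEM: a numeric array indexed
#' `[slice, row, col]` holding 8-bit intensities together with the physical
#' voxel size.
#'
#' Indexing is 1-based `(slice, row, col)` throughout the package; slice 1 is
#' the first acquired face.
#'
#' @param data 3D numeric array `[slice, row, col]`; values within
#'   `dtype_range`.
#' @param voxel_size numeric length-3, physical voxel extents `(z, y, x)` in
#'   nanometres; strictly positive. Default `c(50, 10, 10)`, the common
#'   SBF-SEM regime of thin in-plane pixels and thicker cutting steps.
#' @param dtype_range numeric length-2 intensity bounds, default `c(0, 255)`.
#' @return A `volume_stack` object.
#' @export
volume_stack <- function(data, voxel_size = c(50, 10, 10),
                         dtype_range = c(0, 255)) {
  if (length(dim(data)) == 2L) dim(data) <- c(1L, dim(data))
  stopifnot(length(dim(data)) == 3L, all(dim(data) >= 1L))
  if (any(voxel_size <= 0) || length(voxel_size) != 3L)
    stop("voxel_size must be three strictly positive extents (z, y, x)")
  rng <- range(data)
  if (rng[1] < dtype_range[1] || rng[2] > dtype_range[2])
    stop(sprintf("intensities [%g, %g] fall outside dtype_range [%g, %g]",
                 rng[1], rng[2], dtype_range[1], dtype_range[2]))
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 dtype_range = as.numeric(dtype_range)),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_stack> %d slices of %d x %d, voxel %g x %g x %g nm (z,y,x)\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' @export
dim.volume_stack <- function(x) dim(x$data)

#' Semantic label volume
#'
#' A 3D integer class-label array sharing the geometry of its source
#' [volume_stack()]. Classes are mutually exclusive and jointly exhaustive:
#' every voxel carries exactly one code.
#'
#' @param labels 3D integer array `[slice, row, col]`.
#' @param class_codes named integer vector mapping class names to codes.
#'   Default: background 0, cell cytoplasm 1, nucleus 2, neighbour 3.
#' @return A `label_volume` object.
#' @export
label_volume <- function(labels,
                         class_codes = c(background = 0L, cell_cytoplasm = 1L,
                                         nucleus = 2L, neighbour = 3L)) {
  if (length(dim(labels)) == 2L) dim(labels) <- c(1L, dim(labels))
  stopifnot(length(dim(labels)) == 3L)
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(class_codes))
  if (length(bad))
    stop("unknown class codes present: ", paste(bad, collapse = ", "))
  structure(list(labels = labels, class_codes = class_codes),
            class = "label_volume")
}

#' @export
dim.label_volume <- function(x) dim(x$labels)

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  tab <- table(factor(as.vector(x$labels), levels = unname(x$class_codes),
                      labels = names(x$class_codes)))
  cat(sprintf("<label_volume> %d x %d x %d (slice,row,col)\n", d[1], d[2], d[3]))
  print(tab)
  invisible(x)
}

#' Region-of-interest window
#'
#' A requested crop window given by its centre voxel and size. Realized
#' (clipped) coordinates are computed against a parent volume by
#' [crop_roi()]: windows are clipped to the parent, never zero-padded, so
#' cells near the volume faces keep their true intensities.
#'
#' @param center integer length-3 `(slice, row, col)`, 1-based, in parent
#'   coordinates.
#' @param size integer length-3 `(depth, height, width)` in voxels.
#' @return A `roi_window` object.
#' @export
roi_window <- function(center, size) {
  stopifnot(length(center) == 3L, length(size) == 3L, all(size >= 1))
  structure(list(center = as.integer(round(center)), size = as.integer(size),
                 offset = NULL), class = "roi_window")
}

#' Realize a window against a parent shape
#'
#' Clips the requested window to the parent bounds, recording the start
#' corner (`offset`) and the realized size. For every voxel `v` of the crop,
#' `parent[offset + v - 1] == roi[v]`.
#'
#' @param window an [roi_window()].
#' @param parent_shape integer length-3 parent dimensions.
#' @return The window with `offset` and `size` set to realized values.
#' @export
realize_window <- function(window, parent_shape) {
  stopifnot(inherits(window, "roi_window"), length(parent_shape) == 3L)
  ctr <- window$center
  if (any(ctr < 1L) || any(ctr > parent_shape))
    stop(sprintf("window center (%s) outside parent bounds (%s)",
                 paste(ctr, collapse = ","), paste(parent_shape, collapse = ",")))
  ideal_start <- ctr - (window$size %/% 2L)
  start <- pmax(1L, ideal_start)
  end <- pmin(as.integer(parent_shape), ideal_start + window$size - 1L)
  window$offset <- start
  window$realized_size <- end - start + 1L
  window
}

natural_order <- function(x) {
  # sorts z2 before z10: pad every digit run to a fixed width
  key <- gsub("(\\d+)", "~\\1", x)
  parts <- strsplit(key, "~")
  keys <- vapply(parts, function(p) {
    isnum <- grepl("^\\d", p)
    p[isnum] <- sprintf("%020.0f",
                        as.numeric(sub("(\\d+).*", "\\1", p[isnum])))
    paste(p, collapse = "")
  }, character(1))
  order(keys)
}

read_slice_file <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1]  # drop extra channels
  img
}

#' Read an image stack from disk
#'
#' Reads a 3D stack either from a directory of single-slice TIFF files
#' (ordered by natural sort of the filenames, so `z2` precedes `z10`) or from
#' a multi-page TIFF, returning a [volume_stack()] with slices in
#' acquisition order.
#'
#' @param source path to a directory of per-slice TIFFs or to a multi-page
#'   TIFF file.
#' @param voxel_size physical voxel extents `(z, y, x)` in nm.
#' @return A [volume_stack()].
#' @export
read_stack <- function(source, voxel_size = c(50, 10, 10)) {
  if (dir.exists(source)) {
    files <- list.files(source, pattern = "\\.tif{1,2}$", ignore.case = TRUE,
                        full.names = TRUE)
    if (!length(files)) stop("no TIFF files found in ", source)
    files <- files[natural_order(basename(files))]
    slices <- lapply(files, read_slice_file)
    dims <- vapply(slices, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
      stop("slice dimensions differ: ", basename(files[bad]), " is ",
           dims[1, bad], "x", dims[2, bad], " but ", basename(files[1]),
           " is ", dims[1, 1], "x", dims[2, 1])
    }
  } else if (file.exists(source)) {
    pages <- tiff::readTIFF(source, as.is = TRUE, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    slices <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  } else {
    stop("source does not exist: ", source)
  }
  arr <- array(0L, c(length(slices), dim(slices[[1]])))
  for (z in seq_along(slices)) arr[z, , ] <- slices[[z]]
  volume_stack(arr, voxel_size = voxel_size)
}

write_slices <- function(arr, dest, prefix = "z") {
  if (!dir.exists(dest)) dir.create(dest, recursive = TRUE)
  if (file.access(dest, mode = 2) != 0) stop("destination not writable: ", dest)
  nz <- dim(arr)[1]
  files <- character(nz)
  for (z in seq_len(nz)) {
    f <- file.path(dest, sprintf("%s%04d.tiff", prefix, z - 1L))
    tiff::writeTIFF(arr[z, , ] / 255, f, bits.per.sample = 8L,
                    compression = "none")
    files[z] <- f
  }
  files
}

#' Write a label volume as a TIFF stack
#'
#' One single-page 8-bit TIFF per slice, named `z0000.tiff`, `z0001.tiff`,
#' ... so that lexical order equals slice order. Integer class codes are
#' preserved bit-exactly and round-trip through [read_label_stack()].
#'
#' @param vol a [label_volume()].
#' @param dest directory path (created if absent).
#' @return Invisibly, the character vector of files written.
#' @export
write_label_stack <- function(vol, dest) {
  stopifnot(inherits(vol, "label_volume"))
  invisible(write_slices(vol$labels, dest))
}

#' Read a label volume written by [write_label_stack()]
#'
#' @param source directory of per-slice label TIFFs.
#' @param class_codes class-code map, as in [label_volume()].
#' @return A [label_volume()].
#' @export
read_label_stack <- function(source,
                             class_codes = c(background = 0L, cell_cytoplasm = 1L,
                                             nucleus = 2L, neighbour = 3L)) {
  vs <- read_stack(source)
  label_volume(vs$data, class_codes = class_codes)
}

#' Write an intensity volume as a TIFF stack
#'
#' @param vol a [volume_stack()].
#' @param dest directory path (created if absent).
#' @return Invisibly, the files written.
#' @export
write_stack <- function(vol, dest) {
  stopifnot(inherits(vol, "volume_stack"))
  invisible(write_slices(round(vol$data), dest))
}

#' Crop a region of interest out of a volume
#'
#' Restricts the parent volume to the window, clipping at the volume faces
#' (no padding). The realized window records the clip so ROI coordinates map
#' back to parent coordinates via `parent_coord = offset + roi_coord - 1`.
#'
#' @param vol a [volume_stack()] (or [label_volume()]).
#' @param window an [roi_window()].
#' @return A list with elements `roi` (the cropped object, same class as
#'   `vol`) and `window` (the realized [roi_window()]).
#' @export
crop_roi <- function(vol, window) {
  arr <- if (inherits(vol, "label_volume")) vol$labels else vol$data
  w <- realize_window(window, dim(arr))
  idx <- Map(function(o, s) o:(o + s - 1L), as.list(w$offset),
             as.list(w$realized_size))
  sub <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  roi <- if (inherits(vol, "label_volume")) {
    label_volume(sub, class_codes = vol$class_codes)
  } else {
    volume_stack(sub, voxel_size = vol$voxel_size, dtype_range = vol$dtype_range)
  }
  list(roi = roi, window = w)
}
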