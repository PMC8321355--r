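# Shared fixtures, generated in code. Heavier phantoms are cached per test
# run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the standard multi-cell phantom used across detection/pipeline tests
std_phantom <- function() {
  cached("std_phantom",
         generate_phantom(phantom_spec(shape = c(60, 512, 512), n_cells = 5,
                                       seed = 7)))
}

# a single, centred cell: fast nucleus/cell fixtures
single_cell_phantom <- function(seed = 3) {
  cached(paste0("single_", seed), {
    generate_phantom(phantom_spec(shape = c(50, 256, 256), n_cells = 1,
                                  cell_radius = c(60, 70), min_gap = 10,
                                  seed = seed))
  })
}

# a binary disc image
disc_mask <- function(n, center, radius) {
  r <- matrix(seq_len(n), n, n)
  c <- t(r)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

# brute-force Euclidean distance to the nearest background pixel
brute_distance_map <- function(mask) {
  cells <- !mask
  bgidx <- which(mask, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (cells[i, j]) {
        out[i, j] <- sqrt(min((bgidx[, 1] - i)^2 + (bgidx[, 2] - j)^2))
      }
    }
  }
  out
}

# naive per-voxel confusion tally (the oracle for confusion())
naive_confusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i]; t <- truth[i]
    if (p && t) tp <- tp + 1L
    else if (!p && !t) tn <- tn + 1L
    else if (p && !t) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# exhaustive between-class-variance scan (the oracle for otsu_threshold)
brute_otsu <- function(values) {
  best <- -Inf; best_t <- NA
  for (t in 0:254 + 0.5) {
    lo <- values[values < t]; hi <- values[values >= t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(values)
    b <- w0 * (1 - w0) * (mean(hi) - mean(lo))^2
    if (b > best) { best <- b; best_t <- t }
  }
  best_t
}

# ROI around one phantom cell plus its recoded truth
phantom_cell_roi <- function(ph, i, roi_size) {
  cells <- ph$truth$cells
  ctr <- c(round(cells$center_slice[i]), round(cells$center_row[i]),
           round(cells$center_col[i]))
  w <- roi_window(center = ctr, size = roi_size)
  cr <- crop_roi(ph$volume, w)
  list(roi = cr$roi, window = cr$window,
       center_roi = ctr - cr$window$offset + 1L,
       truth = phantom_roi_truth(ph, w, cells$id[i]))
}

# index of the cell farthest from the lateral faces (the one the edge-margin
# rule would keep)
most_interior_cell <- function(ph) {
  cells <- ph$truth$cells
  shape <- dim(ph$volume)
  d <- pmin(cells$center_row - 1, shape[2] - cells$center_row,
            cells$center_col - 1, shape[3] - cells$center_col)
  which.max(d)
}
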