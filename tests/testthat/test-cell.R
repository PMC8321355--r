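make_bg_discs <- function(n, centers, radius) {
  bg <- matrix(TRUE, n, n)
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  for (ct in centers) bg[(rr - ct[1])^2 + (cc - ct[2])^2 <= radius^2] <- FALSE
  bg
}

test_that("watershed separates a dumbbell into two basins at the neck", {
  bg <- matrix(TRUE, 120, 200)
  rr <- matrix(seq_len(120), 120, 200); cc <- t(matrix(seq_len(200), 200, 120))
  bg[(rr - 60)^2 + (cc - 70)^2 <= 40^2] <- FALSE
  bg[(rr - 60)^2 + (cc - 130)^2 <= 40^2] <- FALSE
  ws <- watershed_cells(distance_map(bg))
  expect_equal(max(ws), 2L)
  expect_true(all(ws[bg] == 0L))
  # the split line sits near the narrowest part of the neck (col ~ 100)
  split_cols <- which(apply(ws, 2, function(col) {
    v <- unique(col[col > 0]); length(v) > 1 ||
      (any(col == 0 & !bg[, 1]) && FALSE)
  }))
  boundary <- abs(ws[, 99] - ws[, 101])
  expect_true(any(ws[60, 1:100] != ws[60, 101:200][ws[60, 101:200] > 0][1]))
})

test_that("basin count equals disc count for isolated discs", {
  for (k in 1:6) {
    centers <- lapply(seq_len(k), function(i) c(40, 40 + 70 * (i - 1)))
    n <- 80 + 70 * (k - 1)
    bg <- matrix(TRUE, 80, n)
    rr <- matrix(seq_len(80), 80, n); cc <- t(matrix(seq_len(n), n, 80))
    for (ct in centers) bg[(rr - ct[1])^2 + (cc - ct[2])^2 <= 25^2] <- FALSE
    ws <- watershed_cells(distance_map(bg))
    expect_equal(max(ws), k)
  }
  # an all-background slice yields an empty labelling
  expect_true(all(watershed_cells(matrix(0, 10, 10)) == 0L))
})

test_that("central-region selection honours the anchor and falls back", {
  bg <- make_bg_discs(200, list(c(60, 60), c(60, 150), c(150, 100)), 35)
  ws <- watershed_cells(distance_map(bg))
  m <- select_central_region(ws, anchor = c(60, 150))
  expect_true(m[60, 150])
  expect_equal(sort(unique(ws[m])), ws[60, 150])

  # anchor on background: the large-and-near basin wins
  m2 <- select_central_region(ws, anchor = c(60, 105))
  expect_equal(sum(m2), max(tabulate(ws[ws > 0])[unique(ws[c(m2)])]))
  expect_error(select_central_region(matrix(0L, 5, 5)), "no cell")
  expect_error(select_central_region(ws, anchor = c(999, 1)), "anchor")
})

test_that("opening is anti-extensive and removes thin protrusions", {
  disc <- disc_mask(240, c(120, 100), 100)
  spike <- disc
  spike[118:120, 100:235] <- TRUE   # 3-px wide spike
  opened <- smooth_open(spike, 10)
  expect_true(all(opened <= spike))            # anti-extensive
  expect_false(any(opened[115:125, 225:235]))  # spike gone
  # a disc much larger than the SE is essentially unchanged
  expect_lt(abs(sum(smooth_open(disc, 10)) - sum(disc)) / sum(disc), 0.02)
  expect_error(smooth_open(disc_mask(40, c(20, 20), 4), 10), "se_radius")
})

test_that("opening a wedge-carrying basin increases solidity", {
  disc <- disc_mask(240, c(120, 120), 80)
  wedge <- disc
  for (i in 1:40) wedge[120 + i, 200:(200 + (40 - i))] <- TRUE
  solidity <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    hull <- grDevices::chull(idx)
    area_hull <- abs(sum(idx[hull, 1] * idx[c(hull[-1], hull[1]), 2] -
                         idx[c(hull[-1], hull[1]), 1] * idx[hull, 2])) / 2
    sum(m) / area_hull
  }
  opened <- smooth_open(wedge, 25)
  expect_gt(solidity(opened), solidity(wedge))
})

test_that("protrusions merge; sandwiched and compact regions do not", {
  # core disc with a thin finger surrounded by background
  n <- 200
  bg <- matrix(TRUE, n, n)
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  cell <- (rr - 100)^2 + (cc - 80)^2 <= 50^2
  finger <- rr >= 97 & rr <= 103 & cc >= 80 & cc <= 170
  bg[cell | finger] <- FALSE
  core <- smooth_open(!bg, 20)
  fin <- merge_protrusions(core, bg, surround_frac = 0.8,
                           max_merge_frac = 0.5, merge_max_halfwidth = 7)
  expect_true(all(core <= fin))                 # merging only adds
  expect_true(any(fin[100, 150:168]))           # finger recovered
  lab <- EBImage::bwlabel(fin)
  expect_equal(max(lab), 1L)                    # one connected component

  # a compact blob touching the core is a neighbour body, not an appendage
  bg2 <- matrix(TRUE, n, n)
  blob <- (rr - 100)^2 + (cc - 155)^2 <= 24^2
  bg2[cell | blob] <- FALSE
  core2 <- smooth_open(cell & !blob, 20)
  fin2 <- merge_protrusions(core2, bg2, surround_frac = 0.8,
                            max_merge_frac = 0.5, merge_max_halfwidth = 7)
  expect_lt(sum(fin2 & blob & !cell) / sum(blob & !cell), 0.1)

  # a region sandwiched between core and neighbour with little background
  # stays out (the cautious-boundary behaviour)
  bg3 <- matrix(TRUE, n, n)
  cellA <- (rr - 100)^2 + (cc - 60)^2 <= 45^2
  cellB <- (rr - 100)^2 + (cc - 160)^2 <= 45^2
  strip <- rr >= 70 & rr <= 130 & cc >= 103 & cc <= 117
  bg3[cellA | cellB | strip] <- FALSE
  coreA <- smooth_open(cellA, 20)
  finA <- merge_protrusions(coreA, bg3, surround_frac = 0.8,
                            max_merge_frac = 0.5, merge_max_halfwidth = 7)
  expect_lt(sum(finA & strip & !cellA) / sum(strip & !cellA), 0.2)
})

test_that("volume segmentation yields exclusive classes off-limits to background", {
  ph <- single_cell_phantom()
  fx <- phantom_cell_roi(ph, 1, c(50, 224, 224))
  nuc <- segment_nucleus_volume(fx$roi, seed_slice = fx$center_roi[1],
                                center = fx$center_roi[2:3])
  bg <- lapply(seq_len(dim(fx$roi)[1]), function(z)
    suppressWarnings(segment_background_slice(fx$roi$data[z, , ])))
  lab <- suppressMessages(segment_cell_volume(fx$roi, bg, nucleus = nuc))

  # conservation: every voxel carries exactly one known class
  expect_true(all(lab$labels %in% 0:3))
  # the cell never claims background voxels
  for (z in seq(1, dim(lab)[1], by = 7)) {
    expect_equal(sum(lab$labels[z, , ] %in% 1:2 & bg[[z]]), 0)
  }
  # recovery of the single cell
  ji <- jaccard(confusion(lab$labels %in% 1:2, fx$truth$labels %in% 1:2))
  expect_gte(ji, 0.8)
})

test_that("a backgroundless ROI aborts with the documented limitation", {
  ph <- single_cell_phantom()
  va <- degrade_background(ph, "absent")
  cells <- ph$truth$cells
  ctr <- c(round(cells$center_slice[1]), round(cells$center_row[1]),
           round(cells$center_col[1]))
  fx_vol <- crop_roi(va, roi_window(center = ctr, size = c(10, 200, 200)))$roi
  bg <- lapply(seq_len(dim(fx_vol)[1]), function(z)
    suppressWarnings(segment_background_slice(fx_vol$data[z, , ])))
  expect_error(segment_cell_volume(fx_vol, bg), "background")
})

test_that("touching cells split along a near-straight watershed line", {
  # two overlapping discs with no background corridor between them
  bg <- matrix(TRUE, 160, 260)
  rr <- matrix(seq_len(160), 160, 260); cc <- t(matrix(seq_len(260), 260, 160))
  bg[(rr - 80)^2 + (cc - 90)^2 <= 55^2] <- FALSE
  bg[(rr - 80)^2 + (cc - 180)^2 <= 55^2] <- FALSE
  ws <- watershed_cells(distance_map(bg))
  expect_equal(max(ws), 2L)
  # columns where basin 1 pixels sit next to basin 2 pixels form a narrow,
  # near-vertical band: the bisecting line between the touching pair
  lab_left <- ws[80, 90]; lab_right <- ws[80, 180]
  expect_true(lab_left != lab_right && lab_left > 0 && lab_right > 0)
  bounds <- c()
  for (i in seq_len(160)) {
    row <- ws[i, ]
    if (!any(row == lab_left) || !any(row == lab_right)) next
    j <- max(which(row == lab_left))
    # only rows where the basins are actually in contact (no resin between)
    if (any(row[(j + 1):min(j + 3, length(row))] == lab_right)) {
      bounds <- c(bounds, j)
    }
  }
  expect_gt(length(bounds), 10)
  expect_lt(stats::sd(bounds), 6)
})
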