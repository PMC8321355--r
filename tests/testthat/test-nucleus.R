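test_that("lowpass preserves DC, normalizes mass, and reduces noise variance", {
  p <- ne_params()
  flat <- matrix(123, 32, 32)
  expect_equal(lowpass(flat, p), flat, tolerance = 1e-12, ignore_attr = TRUE)

  # unit impulse: the response is the kernel, total mass 1
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  resp <- lowpass(imp, p)
  expect_lt(abs(sum(resp) - 1), 1e-6)
  expect_equal(max(resp), resp[17, 17])

  set.seed(8)
  noise <- matrix(rnorm(64 * 64, 128, 20), 64, 64)
  expect_lt(stats::var(as.vector(lowpass(noise, p))),
            stats::var(as.vector(noise)))
})

test_that("edge linking bridges gaps into one connected envelope edge", {
  p <- ne_params()
  # two collinear segments with a 4-px gap, drawn as intensity steps
  img <- matrix(100, 40, 60)
  img[20:40, 1:20] <- 200
  img[20:40, 25:60] <- 200   # gap columns 21:24 stay flat
  e <- ne_edge_mask(lowpass(img, p), p)
  lab <- EBImage::bwlabel(e)
  expect_equal(max(lab), 1L)

  # an edgeless slice keeps an empty mask
  expect_false(any(ne_edge_mask(lowpass(matrix(80, 32, 32), p), p)))

  # a ring with small intensity gaps closes into one component
  img2 <- matrix(150, 101, 101)
  rr <- matrix(seq_len(101), 101, 101); cc <- t(rr)
  rho <- sqrt((rr - 51)^2 + (cc - 51)^2)
  ring <- rho >= 28 & rho <= 31
  ang <- atan2(rr - 51, cc - 51)
  gaps <- (abs(ang) < 0.06) | (abs(ang - 2) < 0.06) | (abs(ang + 2) < 0.06)
  img2[ring & !gaps] <- 40
  e2 <- ne_edge_mask(lowpass(img2, p), p)
  lab2 <- EBImage::bwlabel(e2)
  expect_equal(max(lab2), 1L)
})

test_that("slice segmentation recovers the nucleoplasm at the equator", {
  ph <- single_cell_phantom()
  fx <- phantom_cell_roi(ph, 1, c(50, 224, 224))
  z <- fx$center_roi[1]
  m <- segment_nucleus_slice(fx$roi$data[z, , ], center = fx$center_roi[2:3])
  truth <- fx$truth$labels[z, , ] == 2
  expect_gte(jaccard(confusion(m, truth)), 0.9)
  # border rule: nothing touches the slice border
  expect_false(any(m[1, ]) || any(m[nrow(m), ]) ||
                 any(m[, 1]) || any(m[, ncol(m)]))
})

test_that("a prior keeps only overlapping components", {
  p <- ne_params()
  # two bright blobs ringed by dark edges; the prior overlaps only one
  img <- matrix(90, 120, 120)
  rr <- matrix(seq_len(120), 120, 120); cc <- t(rr)
  for (ct in list(c(40, 40), c(80, 85))) {
    rho <- sqrt((rr - ct[1])^2 + (cc - ct[2])^2)
    img[rho <= 22] <- 150
    img[rho > 18 & rho <= 22] <- 40
  }
  prior <- matrix(FALSE, 120, 120); prior[30:50, 30:50] <- TRUE
  m <- segment_nucleus_slice(img, p, prior = prior)
  expect_true(any(m[35:45, 35:45]))
  expect_false(any(m[70:95, 75:95]))
})

test_that("propagation covers the nucleus span and stops at the poles", {
  ph <- single_cell_phantom()
  fx <- phantom_cell_roi(ph, 1, c(50, 224, 224))
  nuc <- segment_nucleus_volume(fx$roi, seed_slice = fx$center_roi[1],
                                center = fx$center_roi[2:3])
  truth3d <- fx$truth$labels == 2
  ji <- jaccard(confusion(nuc$labels == 2, truth3d))
  expect_gte(ji, 0.9)

  # retained slices overlap toward the seed; no mask touches the border
  nz <- dim(nuc)[1]
  areas <- vapply(seq_len(nz), function(z) sum(nuc$labels[z, , ] == 2),
                  numeric(1))
  present <- which(areas > 0)
  expect_true(all(diff(present) == 1))  # one contiguous axial run
  seed_z <- fx$center_roi[1]
  for (z in present[present != seed_z]) {
    toward <- z + sign(seed_z - z)
    expect_gt(sum(nuc$labels[z, , ] == 2 & nuc$labels[toward, , ] == 2), 0)
  }

  # determinism
  nuc2 <- segment_nucleus_volume(fx$roi, seed_slice = fx$center_roi[1],
                                 center = fx$center_roi[2:3])
  expect_identical(nuc$labels, nuc2$labels)
})

test_that("an empty seed slice is a hard, actionable error", {
  ph <- single_cell_phantom()
  fx <- phantom_cell_roi(ph, 1, c(50, 224, 224))
  # seed far beyond the nucleus pole
  expect_error(segment_nucleus_volume(fx$roi, seed_slice = 1),
               "no nucleus found at seed slice")
})

test_that("single-slice ROI reduces to slice segmentation", {
  ph <- single_cell_phantom()
  fx <- phantom_cell_roi(ph, 1, c(50, 224, 224))
  z <- fx$center_roi[1]
  one <- volume_stack(fx$roi$data[z, , , drop = FALSE])
  nuc <- segment_nucleus_volume(one, seed_slice = 1,
                                center = fx$center_roi[2:3])
  ref <- segment_nucleus_slice(fx$roi$data[z, , ], center = fx$center_roi[2:3])
  expect_identical(nuc$labels[1, , ] == 2, unclass(ref), ignore_attr = TRUE)
})

test_that("nucleus segmentation does not need any background", {
  ph <- single_cell_phantom()
  va <- degrade_background(ph, "absent")
  cells <- ph$truth$cells
  ctr <- c(round(cells$center_slice[1]), round(cells$center_row[1]),
           round(cells$center_col[1]))
  w <- roi_window(center = ctr, size = c(50, 224, 224))
  cr <- crop_roi(va, w)
  roi_ctr <- ctr - cr$window$offset + 1L
  nuc <- segment_nucleus_volume(cr$roi, seed_slice = roi_ctr[1],
                                center = roi_ctr[2:3])
  truth <- phantom_roi_truth(ph, w, 1L)
  expect_gte(jaccard(confusion(nuc$labels == 2, truth$labels == 2)), 0.9)
})
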