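test_that("distance_map matches brute force on small grids", {
  set.seed(5)
  for (k in 1:5) {
    n <- sample(24:64, 1)
    mask <- matrix(runif(n * n) < 0.15, n, n)
    if (!any(mask)) mask[1, 1] <- TRUE
    expect_equal(distance_map(mask), brute_distance_map(mask))
  }
})

test_that("distance_map basics: zero on background, 1-Lipschitz, disc peak ~ r", {
  mask <- !disc_mask(101, c(51, 51), 40)  # TRUE = background outside the disc
  d <- distance_map(mask)
  expect_true(all(d[mask] == 0))
  expect_lt(abs(max(d) - 40), 1.1)
  # neighbouring pixels differ by at most sqrt(2)
  expect_lte(max(abs(diff(d))), sqrt(2) + 1e-12)
  expect_lte(max(abs(t(diff(t(d))))), sqrt(2) + 1e-12)

  # single non-background pixel has distance 1
  m1 <- matrix(TRUE, 9, 9); m1[5, 5] <- FALSE
  expect_equal(distance_map(m1)[5, 5], 1)

  # all-background mask gives an all-zero map
  expect_true(all(distance_map(matrix(TRUE, 8, 8)) == 0))
  # no background at all: undefined
  expect_error(distance_map(matrix(FALSE, 8, 8)), "no background")
})

test_that("peaks are detected in size order and suppressed around each peak", {
  # two discs of radius 50 and 30 in background
  bg <- matrix(TRUE, 160, 300)
  r <- matrix(seq_len(160), 160, 300); cl <- t(matrix(seq_len(300), 300, 160))
  bg[(r - 80)^2 + (cl - 80)^2 <= 50^2] <- FALSE
  bg[(r - 80)^2 + (cl - 220)^2 <= 30^2] <- FALSE
  d <- distance_map(bg)
  ref <- brute_distance_map(bg)
  det <- detect_cells_slice(d, n_cells = 2, suppression_radius = 60)
  expect_equal(nrow(det), 2L)
  expect_equal(det$rank, c(1L, 2L))
  # rank 1 is the radius-50 disc, rank 2 the radius-30 disc
  expect_lt(abs(det$peak_height[1] - max(ref[, 1:150])), 1e-9)
  expect_lt(sqrt((det$peak_row[1] - 80)^2 + (det$peak_col[1] - 80)^2), 3)
  expect_lt(sqrt((det$peak_row[2] - 80)^2 + (det$peak_col[2] - 220)^2), 3)
  expect_true(all(diff(det$peak_height) <= 0))

  # asking for more cells than exist exhausts the map
  det20 <- detect_cells_slice(d, n_cells = 20, suppression_radius = 60)
  expect_lte(nrow(det20), 20)
  # pairwise peak distances exceed the suppression radius
  if (nrow(det20) > 1) {
    dmat <- as.matrix(dist(cbind(det20$peak_row, det20$peak_col)))
    expect_gte(min(dmat[upper.tri(dmat)]), 60)
  }

  # a ridge with two maxima inside one suppression radius gives 1 detection
  bg2 <- matrix(TRUE, 80, 120)
  r2 <- matrix(seq_len(80), 80, 120); c2 <- t(matrix(seq_len(120), 120, 80))
  bg2[(r2 - 40)^2 + (c2 - 50)^2 <= 20^2] <- FALSE
  bg2[(r2 - 40)^2 + (c2 - 70)^2 <= 20^2] <- FALSE   # overlapping twin disc
  det1 <- detect_cells_slice(distance_map(bg2), n_cells = 5,
                             suppression_radius = 60)
  expect_equal(nrow(det1), 1L)

  # an all-zero map yields an empty detection table
  expect_equal(nrow(detect_cells_slice(matrix(0, 10, 10), n_cells = 3,
                                       suppression_radius = 5)), 0L)
})

test_that("mutual-nearest linking builds one track per physical cell", {
  # one cell drifting slightly across 5 analysed slices
  det <- dplyr::bind_rows(lapply(1:5, function(k)
    tibble::tibble(slice_index = k * 10, rank = 1L,
                   peak_row = 100 + k, peak_col = 200 - k,
                   peak_height = 50, centroid_row = 100 + k,
                   centroid_col = 200 - k)))
  linked <- link_detections(det, max_lateral_shift = 40)
  expect_equal(length(unique(linked$track_id)), 1L)
  tr <- summarise_tracks(linked)
  expect_equal(tr$n_detections, 5L)

  # two cells far apart stay two tracks
  det2 <- dplyr::bind_rows(det,
    dplyr::mutate(det, peak_row = peak_row + 300, rank = 2L))
  linked2 <- link_detections(det2, max_lateral_shift = 40)
  expect_equal(length(unique(linked2$track_id)), 2L)

  # rank is not identity: a cell whose rank flips across slices still links
  det3 <- tibble::tibble(slice_index = c(1, 1, 2, 2), rank = c(1L, 2L, 1L, 2L),
                         peak_row = c(10, 300, 301, 11),
                         peak_col = c(10, 300, 299, 9),
                         peak_height = c(9, 8, 9, 8),
                         centroid_row = c(10, 300, 301, 11),
                         centroid_col = c(10, 300, 299, 9))
  linked3 <- link_detections(det3, max_lateral_shift = 20)
  expect_equal(length(unique(linked3$track_id)), 2L)
  by_track <- split(linked3$peak_row, linked3$track_id)
  expect_true(any(vapply(by_track, function(x) all(x < 50), logical(1))))

  expect_equal(nrow(link_detections(det[0, ], 10)), 0L)
})

test_that("on the phantom, detection + linking recovers each true cell once", {
  ph <- std_phantom()
  dets <- detect_cells_volume(ph$volume, seq(5, 55, by = 10), n_cells = 5,
                              suppression_radius = 100)
  tracks <- summarise_tracks(link_detections(dets, max_lateral_shift = 40))
  expect_equal(nrow(tracks), 5L)
  cells <- ph$truth$cells
  for (i in seq_len(nrow(cells))) {
    derr <- sqrt((tracks$centroid_row - cells$center_row[i])^2 +
                 (tracks$centroid_col - cells$center_col[i])^2)
    expect_lt(min(derr), 5)
  }
})

test_that("edge-margin selection discards lateral tracks, flags axial ones", {
  tracks <- tibble::tibble(
    track_id = 1:3,
    n_detections = 3L, first_slice = 1, last_slice = 500,
    centroid_slice = c(250, 250, 20),
    centroid_row = c(400, 4000, 4000),
    centroid_col = c(4000, 4000, 4000),
    max_peak_height = 100, detections = list(NULL, NULL, NULL))
  sel <- select_tracks(tracks, c(518, 8192, 8192), edge_margin = 500,
                       axial_margin = 150)
  expect_false(sel$kept[1])         # 400 px from a lateral face
  expect_match(sel$discard_reason[1], "edge")
  expect_true(sel$kept[2])          # central: kept, not partial
  expect_false(sel$partial[2])
  expect_true(sel$kept[3])          # near the top: kept but partial
  expect_true(sel$partial[3])
})

test_that("windows are centred, depth-shifted for partial cells, and clip", {
  tracks <- tibble::tibble(
    track_id = 1:2, n_detections = 3L, first_slice = 1, last_slice = 500,
    centroid_slice = c(259, 30), centroid_row = c(4096, 4096),
    centroid_col = c(4096, 4096), max_peak_height = 100,
    kept = TRUE, partial = c(FALSE, TRUE),
    detections = list(NULL, NULL))
  w <- tracks_to_windows(tracks, c(518, 8192, 8192),
                         roi_size = c(300, 2000, 2000))
  r1 <- realize_window(w$window[[1]], c(518, 8192, 8192))
  expect_equal(r1$realized_size, c(300L, 2000L, 2000L))
  # the near-top track's depth window is shifted to start at slice 1
  r2 <- realize_window(w$window[[2]], c(518, 8192, 8192))
  expect_equal(r2$offset[1], 1L)
  expect_equal(r2$realized_size[1], 300L)
  # laterally still centred on the track
  expect_equal(r2$offset[2] + 1000L, 4096L)
})
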