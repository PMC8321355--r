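#' Specification of a synthetic SBF-SEM phantom
#'
#' Describes a synthetic stack that emulates the imaging regime of
#' resin-embedded cells in serial block-face SEM: a bright, fairly uniform
#' resin background; darker cells as ellipsoids (flattened along z to
#' reflect the anisotropic voxel, which is several times thicker axially
#' than laterally); a nested ellipsoidal nucleoplasm bounded by a dark
#' nuclear-envelope shell; optional tube-like membrane protrusions; and dark
#' organelle speckle inside the cytoplasm so edge detection faces realistic
#' clutter. Gaussian noise is added per class. Ground truth is voxel-exact.
#'
#' @param shape `(depth, height, width)` in voxels; default `c(60, 512, 512)`
#'   keeps full-pipeline runs fast while leaving room for several cells.
#' @param n_cells number of cells to place.
#' @param cell_radius in-plane semi-axis range (px).
#' @param z_radius_factor axial semi-axis as a fraction of the in-plane one;
#'   default 0.2, matching a 10 nm pixel with a 50 nm cutting step.
#' @param nucleus_ratio nucleus-to-cell radius ratio range.
#' @param ne_thickness nuclear-envelope shell thickness (px, in-plane).
#' @param n_protrusions protrusions per cell.
#' @param protrusion_width,protrusion_length width and length ranges (px).
#' @param min_gap minimum in-plane gap (px) between cell surfaces; zero or
#'   negative forces touching/overlapping cells.
#' @param intensities list of `c(mean, sd)` grey levels for `resin`,
#'   `cytoplasm`, `nucleoplasm` and `ne`; resin must be the brightest class
#'   mean (the contrast premise of the whole pipeline).
#' @param speckle_density dark organelle blobs per cytoplasm voxel.
#' @param speckle_radius,speckle_intensity blob radius range (px) and
#'   `c(mean, sd)` grey level.
#' @param seed RNG seed; identical spec + seed reproduces the phantom
#'   bit-exactly.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(60, 512, 512), n_cells = 5,
                         cell_radius = c(55, 75), z_radius_factor = 0.2,
                         nucleus_ratio = c(0.5, 0.6), ne_thickness = 3,
                         n_protrusions = 2, protrusion_width = c(6, 10),
                         protrusion_length = c(25, 50), min_gap = 25,
                         intensities = list(resin = c(200, 5),
                                            cytoplasm = c(90, 15),
                                            nucleoplasm = c(145, 8),
                                            ne = c(45, 8)),
                         speckle_density = 5e-5, speckle_radius = c(2, 4),
                         speckle_intensity = c(50, 10), seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1), n_cells >= 1,
            ne_thickness >= 1)
  if (intensities$resin[1] <= intensities$cytoplasm[1])
    stop("resin must be brighter than cytoplasm")
  if (max(nucleus_ratio) >= 0.95)
    stop("nucleus must fit strictly inside its cell")
  structure(list(shape = as.integer(shape), n_cells = as.integer(n_cells),
                 cell_radius = cell_radius, z_radius_factor = z_radius_factor,
                 nucleus_ratio = nucleus_ratio, ne_thickness = ne_thickness,
                 n_protrusions = n_protrusions,
                 protrusion_width = protrusion_width,
                 protrusion_length = protrusion_length, min_gap = min_gap,
                 intensities = intensities, speckle_density = speckle_density,
                 speckle_radius = speckle_radius,
                 speckle_intensity = speckle_intensity,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

place_cells <- function(spec) {
  nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
  cells <- list()
  for (i in seq_len(spec$n_cells)) {
    ok <- FALSE
    for (try in seq_len(500)) {
      r <- stats::runif(1, spec$cell_radius[1], spec$cell_radius[2])
      rz <- max(3, round(r * spec$z_radius_factor))
      zr <- c(max(rz + 1, 0.3 * nz), min(nz - rz, 0.7 * nz))
      # a cell this large cannot fit in the field at all
      if (r + 5 > ny - r - 5 || r + 5 > nx - r - 5 || zr[1] > zr[2]) next
      cy <- stats::runif(1, r + 5, ny - r - 5)
      cx <- stats::runif(1, r + 5, nx - r - 5)
      cz <- stats::runif(1, zr[1], zr[2])
      clash <- FALSE
      for (c0 in cells) {
        d <- sqrt((cy - c0$cy)^2 + (cx - c0$cx)^2)
        if (d < r + c0$r + spec$min_gap) { clash <- TRUE; break }
      }
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("could not pack ", spec$n_cells,
                  " cells under the gap constraint; enlarge the field or ",
                  "reduce n_cells/min_gap")
    ratio <- stats::runif(1, spec$nucleus_ratio[1], spec$nucleus_ratio[2])
    cells[[i]] <- list(id = i, cz = cz, cy = cy, cx = cx, r = r, rz = rz,
                       nucleus_ratio = ratio)
  }
  cells
}

#' Generate a synthetic phantom volume with ground truth
#'
#' Renders the [phantom_spec()]: cells are placed with bounded rejection
#' sampling under the gap constraint, drawn as anisotropic ellipsoids with
#' nested nucleoplasm and a dark envelope shell, protrusions are attached as
#' in-plane capsules, organelle speckle is scattered in the cytoplasm, and
#' per-class Gaussian noise is applied. Earlier cells keep their voxels
#' where cells overlap (negative `min_gap`), yielding adjacent truth voxels.
#'
#' @param spec a [phantom_spec()].
#' @return A list: `volume` ([volume_stack()]), `truth` (a list with
#'   `labels` — a [label_volume()] with codes background 0, cell 1, nucleus
#'   2 —, `instances` — integer array of per-cell ids, 0 outside cells —
#'   and `cells`, a tibble of centres/radii), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
    cls <- array(0L, spec$shape)
    inst <- array(0L, spec$shape)
    mu <- array(spec$intensities$resin[1], spec$shape)
    sdev <- array(spec$intensities$resin[2], spec$shape)
    cells <- place_cells(spec)

    for (cell in cells) {
      rn <- cell$nucleus_ratio * cell$r
      rnz <- max(2, round(cell$nucleus_ratio * cell$rz))
      zs <- max(1, ceiling(cell$cz - cell$rz)):min(nz, floor(cell$cz + cell$rz))
      for (z in zs) {
        s <- (z - cell$cz) / cell$rz
        if (abs(s) >= 1) next
        r_z <- cell$r * sqrt(1 - s^2)
        rs <- max(1, floor(cell$cy - r_z)):min(ny, ceiling(cell$cy + r_z))
        csq <- max(1, floor(cell$cx - r_z)):min(nx, ceiling(cell$cx + r_z))
        rho <- sqrt(outer((rs - cell$cy)^2, (csq - cell$cx)^2, "+"))
        sn <- (z - cell$cz) / rnz
        rn_z <- if (abs(sn) < 1) rn * sqrt(1 - sn^2) else -1
        sub_cls <- cls[z, rs, csq]
        sub_inst <- inst[z, rs, csq]
        sub_mu <- mu[z, rs, csq]
        sub_sd <- sdev[z, rs, csq]
        free <- sub_inst == 0L & rho <= r_z
        cyto <- free & rho > rn_z + spec$ne_thickness
        ring <- free & rho > rn_z & rho <= rn_z + spec$ne_thickness & rn_z > 0
        nucl <- free & rho <= rn_z
        sub_cls[cyto | ring] <- 1L
        sub_cls[nucl] <- 2L
        sub_inst[free] <- cell$id
        sub_mu[cyto] <- spec$intensities$cytoplasm[1]
        sub_sd[cyto] <- spec$intensities$cytoplasm[2]
        sub_mu[ring] <- spec$intensities$ne[1]
        sub_sd[ring] <- spec$intensities$ne[2]
        sub_mu[nucl] <- spec$intensities$nucleoplasm[1]
        sub_sd[nucl] <- spec$intensities$nucleoplasm[2]
        cls[z, rs, csq] <- sub_cls
        inst[z, rs, csq] <- sub_inst
        mu[z, rs, csq] <- sub_mu
        sdev[z, rs, csq] <- sub_sd
      }
      # tube-like protrusions at the cell equator
      for (p in seq_len(spec$n_protrusions)) {
        theta <- stats::runif(1, 0, 2 * pi)
        w <- stats::runif(1, spec$protrusion_width[1], spec$protrusion_width[2])
        len <- stats::runif(1, spec$protrusion_length[1],
                            spec$protrusion_length[2])
        z0 <- round(cell$cz + stats::runif(1, -0.3, 0.3) * cell$rz)
        u <- c(sin(theta), cos(theta))
        p1 <- c(cell$cy, cell$cx) + 0.7 * cell$r * u
        p2 <- c(cell$cy, cell$cx) + (cell$r + len) * u
        for (z in max(1, z0 - 1):min(nz, z0 + 1)) {
          rs <- max(1, floor(min(p1[1], p2[1]) - w)):min(ny, ceiling(max(p1[1], p2[1]) + w))
          csq <- max(1, floor(min(p1[2], p2[2]) - w)):min(nx, ceiling(max(p1[2], p2[2]) + w))
          if (!length(rs) || !length(csq)) next
          yy <- matrix(rs, length(rs), length(csq))
          xx <- matrix(csq, length(rs), length(csq), byrow = TRUE)
          v <- p2 - p1
          tt <- pmin(1, pmax(0, ((yy - p1[1]) * v[1] + (xx - p1[2]) * v[2]) /
                               sum(v^2)))
          dseg <- sqrt((yy - (p1[1] + tt * v[1]))^2 +
                       (xx - (p1[2] + tt * v[2]))^2)
          hit <- dseg <= w / 2 & inst[z, rs, csq] == 0L
          if (!any(hit)) next
          sub_cls <- cls[z, rs, csq]; sub_inst <- inst[z, rs, csq]
          sub_mu <- mu[z, rs, csq]; sub_sd <- sdev[z, rs, csq]
          sub_cls[hit] <- 1L
          sub_inst[hit] <- cell$id
          sub_mu[hit] <- spec$intensities$cytoplasm[1]
          sub_sd[hit] <- spec$intensities$cytoplasm[2]
          cls[z, rs, csq] <- sub_cls; inst[z, rs, csq] <- sub_inst
          mu[z, rs, csq] <- sub_mu; sdev[z, rs, csq] <- sub_sd
        }
      }
    }

    # organelle speckle: dark blobs scattered through the cytoplasm
    cyto_idx <- which(cls == 1L)
    n_spk <- round(spec$speckle_density * length(cyto_idx))
    if (n_spk > 0) {
      at <- sample(cyto_idx, n_spk)
      coords <- arrayInd(at, spec$shape)
      for (k in seq_len(n_spk)) {
        rad <- stats::runif(1, spec$speckle_radius[1], spec$speckle_radius[2])
        z <- coords[k, 1]
        rs <- max(1, coords[k, 2] - ceiling(rad)):min(ny, coords[k, 2] + ceiling(rad))
        csq <- max(1, coords[k, 3] - ceiling(rad)):min(nx, coords[k, 3] + ceiling(rad))
        rho <- sqrt(outer((rs - coords[k, 2])^2, (csq - coords[k, 3])^2, "+"))
        blob <- rho <= rad & cls[z, rs, csq] == 1L
        sub_mu <- mu[z, rs, csq]; sub_sd <- sdev[z, rs, csq]
        sub_mu[blob] <- spec$speckle_intensity[1]
        sub_sd[blob] <- spec$speckle_intensity[2]
        mu[z, rs, csq] <- sub_mu; sdev[z, rs, csq] <- sub_sd
      }
    }

    data <- mu + stats::rnorm(length(mu)) * sdev
    data <- array(round(pmin(255, pmax(0, data))), spec$shape)
    cells_tbl <- purrr::map_dfr(cells, function(cc)
      tibble::tibble(id = cc$id, center_slice = cc$cz, center_row = cc$cy,
                     center_col = cc$cx, radius = cc$r, z_radius = cc$rz,
                     nucleus_radius = cc$nucleus_ratio * cc$r))
    list(volume = volume_stack(data),
         truth = list(labels = label_volume(cls,
                        class_codes = c(background = 0L, cell_cytoplasm = 1L,
                                        nucleus = 2L)),
                      instances = inst, cells = cells_tbl),
         spec = spec)
  })
}

#' Degrade or remove the resin background of a phantom
#'
#' Emulates tightly packed samples with little or no embedding resin
#' visible. `mode = "thin"` re-renders resin at cytoplasm statistics except
#' for a corridor about 2 px wide along the midlines between cells (the
#' boundaries of the nearest-cell partition), so cells remain separated by a
#' sliver of background. `mode = "absent"` paints every resin voxel at
#' cytoplasm statistics: nuclear-envelope segmentation must still work there,
#' while plasma-membrane segmentation fails by design. Truth labels are not
#' altered.
#'
#' @param phantom the list returned by [generate_phantom()].
#' @param mode `"none"`, `"thin"` or `"absent"`.
#' @return A [volume_stack()] with re-rendered intensities.
#' @export
degrade_background <- function(phantom, mode = c("none", "thin", "absent")) {
  mode <- match.arg(mode)
  vol <- phantom$volume
  if (mode == "none") return(vol)
  spec <- phantom$spec
  cls <- phantom$truth$labels$labels
  data <- vol$data
  with_seed(spec$seed + 1L, {
    resin <- cls == 0L
    paint <- resin
    if (mode == "thin") {
      inst <- phantom$truth$instances
      for (z in seq_len(dim(data)[1])) {
        seeds <- inst[z, , ]
        if (!any(seeds > 0)) next
        vor <- EBImage::propagate(matrix(0, nrow(seeds), ncol(seeds)), seeds)
        vor <- matrix(as.integer(vor), nrow(seeds))
        corridor <- (vor != shift_mat(vor, 1, 0, fill = NA) |
                     vor != shift_mat(vor, 0, 1, fill = NA))
        corridor[is.na(corridor)] <- FALSE
        corridor <- dilate1(corridor)
        paint[z, , ] <- paint[z, , ] & !corridor
      }
    }
    n <- sum(paint)
    if (n > 0) {
      data[paint] <- round(pmin(255, pmax(0,
        spec$intensities$cytoplasm[1] +
          stats::rnorm(n) * spec$intensities$cytoplasm[2])))
    }
    volume_stack(data, voxel_size = vol$voxel_size)
  })
}

#' Ground-truth labels for one cell's ROI
#'
#' Crops the phantom truth to a window and recodes it for single-instance
#' evaluation: voxels of the central cell keep classes cell/nucleus, voxels
#' of every other cell become class neighbour (3).
#'
#' @param phantom the list returned by [generate_phantom()].
#' @param window an [roi_window()].
#' @param cell_id instance id of the central cell.
#' @return A [label_volume()] in ROI coordinates.
#' @export
phantom_roi_truth <- function(phantom, window, cell_id) {
  labs <- phantom$truth$labels$labels
  inst <- phantom$truth$instances
  w <- realize_window(window, dim(labs))
  idx <- Map(function(o, s) o:(o + s - 1L), as.list(w$offset),
             as.list(w$realized_size))
  sub <- labs[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  sub_inst <- inst[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  sub[sub_inst != 0L & sub_inst != cell_id] <- 3L
  label_volume(sub)
}
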