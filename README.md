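# vemseg — unsupervised cell instance segmentation for volume electron microscopy

`vemseg` detects, crops and instance-segments whole cells and their nuclei
in serial block-face scanning electron microscopy (SBF-SEM) stacks of
resin-embedded cultured cells (e.g. HeLa), entirely with classical,
training-free image processing. It is written for microscopists and image
analysts who have an aligned 3D stack in which the embedding resin images
brighter than the cells, and who want per-cell label volumes and
quantitative quality scores without annotating training data.

## The method in brief

1. **Background**: each analysed slice is split into Canny-edge
   super-pixels; a super-pixel is resin when its median intensity exceeds
   the Otsu threshold; morphological cleanup yields the background mask.
2. **Detection**: the Euclidean distance transform `D(x) = min_{b in B}
   ||x − b||` (distance to the nearest background pixel) turns each cell
   into a hill whose peak height tracks cell size; greedy peak-picking with
   non-maximum suppression ranks the cells of each slice.
3. **Linking**: peaks on consecutive analysed slices are joined by
   mutual-nearest-neighbour matching into one track per physical cell;
   tracks within 500 px of a lateral face are discarded, and each kept
   track yields a 300 × 2000 × 2000 crop centred on its 3D centroid.
4. **Nucleus**: Gaussian low-pass (h = 7, σ = 2), Canny edges thickened by
   an adaptive linking distance, selection of the large central super-pixel,
   then bidirectional slice propagation from the nucleus equator with an
   overlap test.
5. **Cell**: watershed of the distance map separates touching cells; the
   central basin is opened with a large structuring element and membrane
   protrusions are merged back under a surrounded-by-background test.
6. **Evaluation**: voxel confusion counts feed
   `AC = (TP + TN) / (TP + TN + FP + FN)` and `JI = TP / (TP + FP + FN)`
   for three scenarios — cell excluding nucleus, cell including nucleus,
   nucleus only.

A parametric phantom generator (`generate_phantom()`) renders synthetic
stacks with voxel-exact ground truth in the same imaging regime, so the
whole pipeline is testable at desk scale.

## Worked example

```r
library(vemseg)

# a synthetic 60 x 512 x 512 stack with five cells and exact ground truth
ph  <- generate_phantom(phantom_spec(shape = c(60, 512, 512), n_cells = 5,
                                     seed = 7))

# detect on every 10th slice, link, summarise
dets   <- detect_cells_volume(ph$volume, seq(5, 55, by = 10), n_cells = 5,
                              suppression_radius = 100)
tracks <- summarise_tracks(link_detections(dets, max_lateral_shift = 40))
nrow(tracks)
#> [1] 5

# crop one ROI, segment nucleus then cell, and score it
cells <- ph$truth$cells
ctr   <- round(c(cells$center_slice[1], cells$center_row[1], cells$center_col[1]))
w     <- roi_window(center = ctr, size = c(60, 224, 224))
cr    <- crop_roi(ph$volume, w)
seedz <- ctr[1] - cr$window$offset[1] + 1
nuc   <- segment_nucleus_volume(cr$roi, seed_slice = seedz)
bg    <- lapply(seq_len(dim(cr$roi)[1]), function(z)
  segment_background_slice(cr$roi$data[z, , ]))
lab   <- segment_cell_volume(cr$roi, bg, nucleus = nuc)

evaluate_scenarios(lab, phantom_roi_truth(ph, w, 1))
#>   scenario              tp      tn     fp   fn     ac     ji
#> 1 cell_excl_nucleus 299716 2154123  2725 2060 0.9981 0.9843
#> 2 cell_incl_nucleus 351294 2105102   168 2060 0.9991 0.9937
#> 3 nucleus_only       49021 2407046     0 2557 0.9990 0.9504
```

The scenario table reads: the cell including its nucleus overlaps the
ground truth at Jaccard 0.994, the nucleus alone at 0.950, and in the
cell-including-nucleus scenario false positives (168 voxels) are an order
of magnitude rarer than false negatives (2060): the merge step
deliberately leaves ambiguous cell–cell territory unassigned, so the
segmentation is a cautious lower bound of the cell.

`autoplot()` on the scenario report draws the AC/JI bars; `plot_tracks()`
maps the linked detections over the stack footprint; `overlay_export()`
writes per-slice composites (cells red, nuclei green) and FP/FN shaded
comparison images.

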