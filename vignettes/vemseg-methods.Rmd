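---
title: "Unsupervised cell instance segmentation in volume EM: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised cell instance segmentation in volume EM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Serial block-face scanning electron microscopy (SBF-SEM) images a
resin-embedded sample by repeatedly cutting the block face and scanning the
exposed surface, producing an aligned 3D stack — typically hundreds of
slices of thousands-by-thousands pixels, with voxels several times thicker
axially (the cutting step, ~50 nm) than laterally (~10 nm). For cultured
cells such as HeLa, the embedding resin images *bright and fairly uniform*,
while cells image darker with rich internal texture. `vemseg` exploits
exactly this contrast to find, crop, and instance-segment whole cells and
their nuclei without any training data: every stage is classical image
processing with interpretable parameters.

The pipeline is:

1. **Background segmentation** (per slice): Otsu threshold + Canny-edge
   super-pixels + morphological cleanup → binary resin mask.
2. **Detection and ranking**: Euclidean distance transform of the
   non-background region turns each cell into a "hill" whose height grows
   with cell size; greedy peak-picking with non-maximum suppression ranks
   cells by size.
3. **Linking**: peaks on successive analysed slices are chained by
   mutual-nearest-neighbour matching into tracks, one per physical cell;
   tracks too close to the lateral volume faces are discarded, tracks near
   the top/bottom are kept but flagged partial.
4. **ROI cropping**: one fixed-size window per kept track, centred on the
   track's peak-height-weighted 3D centroid.
5. **Nucleus segmentation**: Gaussian low-pass (size 7, sigma 2), Canny
   edges thickened by an adaptive linking distance, super-pixel selection,
   morphological cleanup, and bidirectional slice propagation from the
   nucleus equator with an overlap test.
6. **Cell (plasma membrane) segmentation**: watershed of the distance map,
   central-basin selection, opening with a large structuring element, and
   conditional merging of membrane protrusions.
7. **Evaluation**: voxel-wise Accuracy `AC = (TP+TN)/total` and Jaccard
   `JI = TP/(TP+FP+FN)` under three binarizations: cell excluding nucleus,
   cell including nucleus, nucleus only.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `slice_step` | 20 | slices | how sparsely detection samples the stack |
| `n_cells` | 20 | – | cells sought per analysed slice (the one manual choice) |
| `suppression_radius` | 300 | px | peak suppression; order of a cell radius |
| `max_lateral_shift` | 500 | px | linking tolerance between analysed slices |
| `edge_margin` | 500 | px | lateral discard margin for tracks |
| `roi_size` | 300×2000×2000 | voxels | crop window per cell |
| `gauss_size`, `gauss_sigma` | 7, 2 | px | low-pass before envelope edges |
| `edge_link_base` | 5 | px | edge-linking distance (grows with detector scale) |
| `se_radius` | 30 | px | opening SE; removes watershed wedges and protrusions |
| `surround_frac` | 0.8 | – | boundary fraction in background∪core for a merge |
| `overlap_frac` | 0.3 | – | prior-overlap fraction sustaining nucleus propagation |

Defaults are stated for the 10 nm/px acquisition scale; the length-like
parameters (`suppression_radius`, `max_lateral_shift`, `se_radius`,
`edge_margin`, `roi_size`) scale linearly with expected cell radius. The
test-suite phantoms use cells of ~60 px radius and scale them accordingly
(e.g. `se_radius` 20–30, `suppression_radius` 70–100).

## Design choices in detail

**Coordinates.** Everything is 1-based `(slice, row, col)`, the R
convention. Crop windows are *clipped* at volume faces, never zero-padded:
cells near the top or bottom of the stack are kept (flagged partial) and
segmented over the slices where they exist.

**Canny thresholds are relative to the maximum gradient.** Gaussian
smoothing at scale `sigma` attenuates a step edge's peak gradient by about
`1/(sigma * sqrt(2*pi))`; absolute grey-level thresholds would therefore
mean different things at different smoothing scales, and at `sigma = 2`
even a full resin/cell step (~110 grey levels) peaks near 22 levels/px.
Hysteresis thresholds are fractions (0.1/0.2 by default) of the maximum
gradient magnitude present, the convention most edge-detector
implementations use. For the faint nuclear envelope, the high threshold is
instead derived automatically by Otsu's split of the gradient-magnitude
distribution, with `low = 0.4 * high`.

**Super-pixel classification.** A super-pixel is background when its
*median* intensity exceeds the Otsu threshold — the median resists the dark
organelle speckle inside cells. Two cleanup rules deserve mention:

* *Contrast guard*: when the two Otsu classes' means are closer than
  `min_contrast` (30 grey levels), the slice has no exploitable contrast; it
  is classified wholesale as resin (mean above `uniform_bright`) or as cell.
  Without the guard, Otsu on a unimodal histogram fabricates a background.
* *Border connectivity*: resin is the embedding medium, so every true
  background region reaches the field border. Bright islands enclosed
  inside cells (a bright nucleoplasm can cross the threshold) are therefore
  not background; without this rule such islands punch holes in the
  distance map and split the watershed.

**Selection of the seed super-pixel ("larger and central").** The nucleus
candidate score is `area / (1 + d)^2` where `d` is the distance from the
ROI centre to the *component itself* (zero when the component contains the
centre). A centroid-based distance fails structurally: the cytoplasm
annulus around the nucleus has its centroid at the ROI centre too, and is
larger.

**Edge-band recovery.** Thickening the envelope edges by the linking
distance consumes a band of the same width around the nucleoplasm
super-pixel; after selection, the mask is dilated by exactly that distance,
returning its boundary to the detected edge line (which sits at the
steepest intensity transition, i.e. the nucleoplasm/envelope interface).

**Nucleus propagation termination.** Each slice's candidates must overlap
the propagated prior by at least `overlap_frac = 0.3` of their own area. A
pure any-overlap rule cannot terminate: one slice beyond the nucleus pole
the candidate is the entire cell interior, which always shares voxels with
the prior while its overlap *fraction* collapses. Setting `overlap_frac =
0` restores any-overlap for data where the stricter rule is too eager.

**Protrusion merging.** A candidate region (non-background, outside the
opened core) merges when it (a) touches the core, (b) has at least
`surround_frac` of its boundary in background∪core, (c) is smaller than
`max_merge_frac` of the core, and (d) is *thin* — it contains no disc of
radius `merge_max_halfwidth` (default `se_radius/3`). The thinness test is
what separates membrane appendages from the compact polar cross-section of
a touching neighbour, which passes (a)–(c) whenever resin rings it. Regions
sandwiched between two cells with little intervening background fail (b)
and stay out: the segmentation is deliberately a *lower bound* of the cell,
and on touching-cell phantoms false negatives outnumber false positives.

**Cell sweep with 3D continuity.** The per-slice cell pipeline sweeps
outward from the nucleus equator; a slice's mask is accepted only if it
overlaps the previous accepted mask by `continuity_frac = 0.3` of the
smaller. Without this, the watershed "finds a cell" on every slice where
any background remains, latching onto neighbours beyond the central cell's
poles.

**Watershed determinism.** Flooding and all tie-breaks are deterministic
(EBImage's implementation plus lexicographic peak tie-breaks in detection),
so a fixed input and configuration reproduce label stacks bit-exactly.

## The phantom generator

Tests and the acceptance script run on parametric phantoms
(`phantom_spec()` / `generate_phantom()`) emulating the imaging regime:
bright uniform resin (200 ± 5), darker cytoplasm (90 ± 15), a brighter
nucleoplasm (145 ± 8) inside a dark envelope shell (45 ± 8, 3 px thick),
ellipsoidal cells flattened axially by the 10:50 voxel anisotropy
(`z_radius_factor = 0.2`), tube-like protrusions, and low-density dark
organelle speckle so the edge stages face clutter. `degrade_background()`
re-renders resin to emulate tightly packed samples: `"thin"` leaves ~2 px
corridors along the midlines between cells; `"absent"` removes the resin
signature entirely (nucleus segmentation must still work; cell segmentation
must refuse, since the distance map is undefined).

What the phantom does *not* model: the electron-optical point-spread
function (boundaries are hard steps plus noise), charging and knife
artefacts, organelle-rich textures (ER, mitochondria) beyond simple
speckle, non-ellipsoidal morphology, and slice-to-slice registration
jitter. Passing on phantoms therefore demonstrates the pipeline's geometric
and topological correctness — detection counts, watershed splitting,
propagation termination, metric algebra, determinism — not its photometric
robustness on real micrographs, where parameter retuning (especially Canny
scales and `min_contrast`) should be expected.

Problem sizes used by the test-suite and acceptance runs: detection and the
full pipeline run on a 60 × 512 × 512 phantom with five cells; nucleus and
touching-cell studies use single-ROI phantoms of 50 × 256 × 256 and
50 × 384 × 384 with per-cell ROIs of 224 × 224 px. These sizes keep a full
suite run to a couple of minutes while leaving every structure (envelope,
protrusions, corridors) several times larger than the morphological scales
involved.

## Degenerate inputs and error conventions

* Constant slice → Otsu is degenerate; the contrast guard classifies the
  slice wholesale.
* All-background mask → all-zero distance map → zero detections (valid).
* No background anywhere in an ROI → `segment_cell_volume()` aborts with
  the documented limitation message; `segment_nucleus_volume()` is
  unaffected.
* Empty seed-slice nucleus → hard error advising a different `seed_slice`.
* Metrics: `accuracy()` errors on zero voxels; `jaccard()` errors on an
  empty union unless `empty_union = "one"` is requested explicitly.
* Equal peak heights in detection break ties by (row, col) order; equal
  watershed flood order is resolved by pixel index — both for determinism.

## Known limitations

* The bright-background premise is load-bearing for cell (not nucleus)
  segmentation; tightly packed tissue requires a different cell-boundary
  cue.
* Watershed bisects genuinely ambiguous inter-cell regions with a straight
  line; disputed protrusions between touching cells are left unassigned
  (cautious false negatives).
* Linking is greedy mutual-nearest-neighbour; no global assignment, no
  handling of division or of cells entering/leaving the field laterally.
* Segmentation is per-slice 2D with 3D consistency constraints, not a true
  3D watershed; heavily tilted elongated cells could shear across slices.
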