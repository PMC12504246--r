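---
title: "Methods: section-to-atlas registration, warping and regional quantification"
author: "sectionatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: section-to-atlas registration, warping and regional quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sectionatlas)
```

# Scope and coordinate conventions

The package operates on three coordinate systems that it keeps deliberately
simple:

* **Atlas space**: continuous 0-based voxel indices of the 3D label grid,
  with voxel centers at integers. Voxel size (micrometers) is metadata; all
  geometry is done in voxel units so that array oracles can verify every
  lookup exactly. Conversion to physical units is a multiplication the
  caller can apply to exported coordinates.
* **Section pixels**: 0-based pixel coordinates of the
  registration-resolution image. A label map is stored as a `height x width`
  integer matrix; pixel `(x, y)` is element `[y + 1, x + 1]`.
* **Section numbers**: the serial ordering carried by the `_sXXX` filename
  token (the last such token wins, which makes parsing deterministic on
  pathological names).

# The affine anchoring model

A section's registration is a cut plane through the atlas: an origin `o`
(the atlas position of pixel `(0, 0)`) and two in-plane spanning vectors
`u` and `v` covering the image's x and y extent,

$$p(x, y) = o + u\,\frac{x}{W-1} + v\,\frac{y}{H-1}.$$

Normalizing by `W - 1` and `H - 1` (rather than `W`, `H`) is a deliberate
design choice: it makes the four image corners map *exactly* to `o`, `o+u`,
`o+v` and `o+u+v`, which gives the model a crisp, testable invariant and an
unambiguous meaning for `u` and `v`. Label lookup is nearest-voxel with
round-half-away-from-zero — labels are categorical, so no interpolation is
meaningful — and any coordinate outside the volume yields background (0).

**Propagation.** Serial registration workflows anchor a few landmark-rich
sections and infer the rest. `propagateSeries()` interpolates `(o, u, v)`
componentwise and linearly in the section number between the two nearest
anchored neighbours; outside the anchored range it extrapolates linearly
from the two nearest anchored sections, replicating when only one section is
anchored. Extrapolation (not clamping) is the default because it is the
continuation of the same linear model; a `clamp` argument (and CLI flag)
replicates the boundary anchoring instead, for series whose ends are known
to be cut parallel.

**Estimation.** `estimateAnchoring()` solves the same model by least squares
from `>= 3` pixel-to-atlas correspondences (QR decomposition, rank check).
Three exact non-collinear correspondences recover the anchoring to machine
precision; this is the parameter-recovery oracle the tests lean on.

# Piecewise-linear warping

Nonlinear in-plane refinement is modelled with displacement markers, each a
*target* (where the anchor point was dragged to) and a *source* (where it
started). `buildWarp()`:

1. auto-inserts the four image corners as fixed markers (source = target)
   unless a user marker already occupies that corner — this guarantees the
   triangulation covers the whole image, a boundary policy the package
   declares explicitly;
2. computes a Delaunay triangulation over the target points.

No Delaunay implementation is available among the package's allowed
dependencies, and the triangulation is central to the algorithm, so the
package implements incremental Bowyer–Watson insertion directly. Marker
sets are tiny (corners plus a handful of anchor points), so the O(n²)
insertion cost is irrelevant. Numerical policy: the in-circumcircle
predicate is evaluated on coordinates translated to the query point and
scaled to order 1, with a strict positive tolerance (`1e-12`), so exactly
cocircular configurations — the four image corners are one — keep the
current diagonal rather than producing overlapping triangles. Triangle
triples are rotated (smallest vertex first) and sorted for deterministic
output.

`warpLookup()` finds each target pixel's containing triangle (ties on shared
edges resolve to the lowest triangle index; by barycentric continuity the
result is identical, so the tie-break is purely for determinism) and
evaluates the same barycentric coordinates over the source triangle.
`warpedLabelMap()` composes this with the affine anchoring and nearest-voxel
lookup, i.e. it samples the *original linear* atlas slice — matching the
refinement model where markers deform the atlas overlay, not the section
image. Folding markers (a source triangle with inverted orientation) are
permitted because lookup lives in target space and remains single-valued; a
warning is emitted since folds usually indicate an input mistake.

# Regional quantification

`quantifySection()` tallies a binary segmentation against a section label
map, after three optional transformations: hierarchy collapse, hemisphere
masking, and nearest-neighbour resampling of the segmentation to the label
map grid (nearest-neighbour preserves binarity).

**Hierarchy collapse.** Reporting ("parent") regions are any antichain of
hierarchy nodes; every node maps to its nearest selected ancestor-or-self,
unselected subtrees map to background. Selecting nested ids is rejected as
ambiguous. The mapping is idempotent and its image has at most
`|selection| + 1` values — both enforced by property tests.

**Objects.** Objects are 8-connected components of the foreground (a small
Rcpp routine; the 4-connected labelers in available image packages do not
match the 8-connectivity rule). Two counting modes are provided because the
"right" rule at region boundaries is genuinely open:

* `split` (default): components are computed *after* region splitting, so
  each maximal connected run within one reporting region is one object
  there. Pixel tallies then conserve exactly
  (`sum(object_pixels) + background = total foreground`) and
  `object_pixels <= region_pixels` always holds.
* `centroid`: whole components are assigned to the region under the
  component centroid (rounded to the nearest pixel). Counts are then
  whole-object counts, but a region's object pixels may exceed its own
  pixel count; the class validity check is relaxed accordingly.

`load = object_pixels / region_pixels` with the `0/0 -> 0` convention is the
bounded, aggregation-stable region-fraction metric. Aggregation across
sections sums pixels and recomputes the load — never averages per-section
loads, which would weight a 10-pixel and a 10,000-pixel section equally.

**Hemisphere masks.** The midsagittal plane is *declared* atlas metadata
(axis + plane coordinate in voxel units), not inferred from symmetry —
inference would silently fail on asymmetric or cropped atlases. A pixel is
"left" when its atlas coordinate along the midline axis is strictly below
the plane; on-plane coordinates count as "right", a fixed tie convention
documented for reproducibility. When markers are present the pixel is pushed
through the warp first, so masks respect deformations around the midline.

# QC by systematic sampling

`generateGrid()` lays a regular point lattice (spacing, offset) over the
section, enumerated row-major, with background points prefilled `outside`.
Assessments use the five-label vocabulary `accurate / inaccurate /
uncertain / damage / outside`; `uncertain` is excluded from accuracy
denominators — the conservative convention when the statistic's exact
definition is open — and this is stated in the report header itself.
Damage is reported per section (`damage / in-tissue points`) and per region
(damage among the region's points over the region's points); sections and
regions above a damage threshold are listed for exclusion. Note the exact
lattice-count identity: per axis the grid has `floor((dim-1)/s) + 1` points,
so halving the spacing turns an `a x b` grid into at least a
`(2a-1) x (2b-1)` grid (not always a full 4x).

# Point clouds

`extractPoints()` composes warp lookup, the affine anchoring, and
nearest-voxel region lookup; out-of-volume points get region 0 plus an
`outside` flag rather than an error, since markers near tissue edges are
routine. Marker pixels are interpreted at registration resolution; callers
with full-resolution coordinates scale first (a CLI `--scale` flag).
Exports are a flat-triplet viewer JSON (`{"name", "color", "points":
[x,y,z, ...]}`) and an RFC-4180 CSV with pixel, coordinate and region
columns; both round-trip value-identically, and coordinates stay in voxel
units for internal consistency. A "keep points between two parallel planes"
filter is included as pure geometry.

# The synthetic-data generator

All tests run against generated data with known ground truth; nothing is
downloaded. The generator emulates the *geometry* of the problem, not
histology:

* `synthAtlas()`: a mirror-symmetric label volume (default
  `64 x 80 x 56` voxels at 25 µm, a typical registration-resolution scale)
  with nested ellipsoidal cortex/subcortex shells and seeded spherical
  nuclei per hemisphere; hierarchy root → {left, right} → structures. Exact
  mirror symmetry (left id `k` ↔ right id `k + 100`) is what makes
  hemisphere-balance assertions exact.
* `synthSeries()`: evenly spaced coronal-like (or fixed-tilt oblique)
  anchorings along the second axis between 20% and 80% of its extent —
  anchorings are affine in the section index by construction — with
  grayscale renders (region-id shading plus Gaussian noise, sd 0.02) and
  optional random displacement markers.
* `synthSegmentation()`: non-overlapping lattice disks planted fully inside
  requested regions. The in-region margin is implemented as the disk
  footprint dilated by the 8-neighbourhood, so no disk pixel is 8-adjacent
  to anything outside its region; centers are kept more than `2r + 2`
  apart. Consequently `split` and `centroid` counting agree exactly on
  fixtures, and planted counts/pixel totals are recovered exactly.

Every generator is a pure function of its seed and parameters (the RNG
state is saved and restored around each call), so fixtures are bit-identical
across reruns. What passing these tests does *not* show: robustness to
stain texture, tears, folds, lighting gradients, or segmentation errors —
real histology properties the generator deliberately omits.

# Problem sizes and numerical tolerances

The shipped tests and the acceptance script use a 16³ random-label atlas for
oracle comparisons (100 random anchorings, exact equality), 1,000 random
anchorings for corner exactness (exact), 50 random pixels against the
per-triangle affine oracle (`< 1e-9`), noise sd 0.5 voxels at n = 20 for
parameter recovery (`u`, `v` within 5%), 100 random segmentations for
conservation (exact), and a five-section `64 x 80 x 56` simulated fixture
for the end-to-end run. These sizes were chosen as the smallest instances
that still exercise every code path with comfortable statistical margins.

# Known limitations

* The on-disk descriptor dialect is this package's own; an import shim for
  the file formats of existing interactive registration tools would be
  needed for interoperability, since those schemas are not published in a
  normative form.
* Hemisphere masking requires declared midline metadata; atlases without it
  simply cannot be masked.
* Label-id image export uses 16-bit TIFF, capping region ids at 65,535.
* Object counting is per section; no 3D object bridging across sections.
* The warp is in-plane only and per section; markers do not propagate
  between sections.
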