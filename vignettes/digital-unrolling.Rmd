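---
title: "Digital unrolling of deformed tubes: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital unrolling of deformed tubes: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclorama)
```

## The problem

Many biological structures are roughly tubular with features that extend
radially through a wall of non-uniform thickness: colonic crypts in the
gut mucosa, annual cementum layers in tooth roots, osteocyte networks in
the shafts of long bones. Micro-CT images such samples intact, but the
interesting features then live on curved, nested shells inside a
deformed tube, and no single planar re-slice shows a tissue layer in one
piece. `cyclorama` digitally unrolls such a tube: it re-forms the wall
into a family of nested, onion-like re-slicing surfaces at fixed
*relative* depths (0% = inner boundary, 100% = outer boundary), maps
each surface onto a planar panorama of common size, and stacks the
panoramas into a "3D cyclorama". Because all panoramas share the same
dimensions, a feature can be followed across tissue depths by paging
through the stack, and annotations made on the panoramas can be carried
back into the voxel grid by the exact inverse of the mapping.

## The model

### Electrostatic meshing of the wall

On each selected cross section the user supplies a closed inner and
outer boundary contour. Both are resampled to `I` equidistant points;
index pairing between the two boundaries is fixed by rotating the outer
contour so that its first point is nearest the inner contour's first
point. The inner points are treated as virtual positive unit charges,
the outer points as negative charges of magnitude `rigidity`. A field
line is traced from every inner point `i`:

* the first step of length `delta` follows the boundary normal into the
  wall (this sidesteps the field singularity at the starting charge);
* every further step moves `delta` along the direction of the electric
  field evaluated at the tip of the previous step, summing inverse-square
  contributions from the `2w + 1` charges per boundary in a sliding
  window centred on `i` (the physical prefactor is irrelevant because
  only the direction is used);
* tracing stops when the point lands on or beyond the outer boundary
  (*complete*) or after `k_max` steps (*stray*). Afterwards the scatter
  variance of the traced points is computed; lines with variance below
  `v_min` (and lines whose first step cannot be placed) are *collapsed*.
  Stray and collapsed lines are discarded and reported.

Electrostatic field lines never cross and meet charged boundaries
perpendicularly, so the surviving polylines are a natural non-crossing
mesh of the wall. The length `d_i` of a complete line — with its final
segment clipped at the exact outer-polygon intersection — is the local
wall thickness at point `i`.

### Internal contours, depth levels and vertical interpolation

Each complete line is re-represented as a cubic spline and sampled at
the absolute depths `c/(C-1) * d_i`, `c = 0..C-1`; for `C = 3` the
relative levels are 0%, 50%, 100%, for `C = 4` they are 0%, 33%, 67%,
100%. For every level a closed periodic cubic spline through the
samples (in surviving-index order, so gaps left by removed lines are
bridged smoothly) is resampled to `I` points — the internal contour.
Because tracing is the expensive step it runs only on every `m`-th
slice; contours on the slices in between come from natural cubic
splines fitted vertically through corresponding points of the key-slice
contours. The last slice is always added to the key set so the vertical
splines interpolate and never extrapolate.

### Mapping to panoramas and the inverse

The rounded perimeter `L_hc` of every contour is computed, and the
global maximum defines the common panorama length `L`. Each contour is
resampled to `L_hc` points, cut open at the point whose azimuth about
the rotation axis `O` is closest to pi radians (ties to the lowest
index), stretched to exactly `L` equidistant points, and used to sample
its image slice bilinearly (nearest-neighbour is available for label
volumes). Stretching every contour to the longest one trades local
scale fidelity for panoramas of identical size: distances must not be
measured on a cyclorama, but topology — the neighbourhood order of
features — is preserved by construction, and no registration between
depth levels is ever needed. The sampled grey values fill the array
`G[l, h, c]`; the continuous source coordinates of every cell are kept
at full precision, so the inverse map is simply a per-cell lookup
followed by rounding, optionally dilating each voxel to a cube (edge 5
is the conventional seed size for region-growing segmentation).

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `I` (`n_points`) | points per contour | 200 | azimuthal resolution; azimuth error of recovered features scales with 360°/I |
| `w` (`window`) | charge half-window | 15 | 31 charges per boundary; larger = better field estimate, slower |
| `delta` | step size (px) | 2 | keep below the thinnest wall; thickness quantization is removed by final-segment clipping |
| `rigidity` | outer/inner charge ratio | 1 | >1 stiff, straighter lines; <1 flexible lines that hug a convoluted outer boundary |
| `k_max` | max steps | 75 | stray-line cutoff; must exceed (max thickness)/delta |
| `v_min` | min scatter variance (px²) | 50 | collapsed-line cutoff |
| `m` | interpolation interval (slices) | 20 | tracing runs on every m-th slice |
| `C` (`n_levels`) | depth levels | 30 | radial resolution; depth recovery is quantized to 1/(C-1) |
| `O` (`origin`) | rotation axis | inner centroid | must stay inside every inner contour |

## Numerical choices

* **Coordinates.** Image coordinates with x = column, y = row; pixel
  (r, c) has its centre at (x = c, y = r), 1-based.
  "Counter-clockwise" is defined once as positive shoelace signed area
  in this frame, which is the direction of increasing azimuth
  `atan2(y - oy, x - ox)`.
* **Equal-chord resampling.** "Equidistant" resampling is piecewise
  linear, iterated to its fixed point where all consecutive vertex
  spacings are equal (tolerance 1e-9, at most 30 sweeps). A single
  arc-length pass is not idempotent — corner cutting redistributes arc
  positions — whereas the fixed point makes `normalize_contour()` and
  the identity case of `stretch_contour()` exactly stable.
* **Membership.** Annulus membership uses the even-odd rule with both
  boundaries excluded, so a field line stepping exactly onto the outer
  boundary terminates cleanly. A point inside the *inner* polygon is
  not a termination: such a line keeps stepping and is caught by the
  stray/collapsed filters.
* **Splines.** In-plane closed curves use periodic cubic splines,
  vertical interpolation and field-line re-representation use natural
  ones; positions along a field line use the cumulative chordal
  parameter of the fitted spline (with `delta = 2` px segments the
  difference from true arc length is far below the pixel scale).
* **Singularities.** Field evaluation within 1e-9 px of a charge raises
  an error; the tracer treats it as a stalled (stray) line. The first
  step never evaluates the field at all.
* **Ties.** The polar opening rounds azimuth gaps to 1e-6 rad before
  taking the argmin, so exact geometric ties resolve to the lowest
  index deterministically rather than by floating-point noise.
* **Degenerate input.** Contours with fewer than 3 distinct vertices or
  zero perimeter, windows with `2w + 1 > I`, `C < 2`, a rotation axis
  outside an inner contour, and fewer than 4 surviving lines per slice
  all raise classed errors before or during the affected stage.

## Design decisions that were genuinely open

* **Explicit stepping.** The incremental construction can be read with
  the field evaluated at the point being defined (implicit) or at the
  tip of the previous increment (explicit). The explicit form is
  implemented: it is what an iterative construction can actually
  compute, and it matches the described build-up of lines segment by
  segment.
* **Clipped thickness.** `d_i` includes the final segment clipped at
  the exact outer-polygon intersection rather than a whole number of
  steps, removing up to `delta` of quantization from the thickness
  estimate. `trace_field_line(clip = FALSE)` reproduces the whole-step
  convention.
* **Start-point pairing.** Pairing "via appropriate selection of the
  starting points" is realised as the nearest-point rule: the outer
  start is the outer point nearest the inner start. It is one
  reasonable reading; any consistent pairing works, and the rule is
  applied identically on every slice so vertical correspondence holds.
* **Gaps from removed lines** are bridged by fitting the per-level
  periodic spline through the surviving samples in cyclic order of
  their original index — the contour closes smoothly across a gap
  rather than being re-parameterised.
* **Variance filter scope.** The collapsed-line test is applied to
  every traced line after the step-count test, not only to short
  stalled ones; with sane `v_min` a genuinely complete line always
  passes it.
* **Charge signs.** Inner positive, outer negative, which orients all
  lines inner-to-outer. Only the ratio (`rigidity`) matters.

## The phantom generator

`phantom_spec()` / `make_tube()` render tubes with known geometry:
constant or linearly tapering radii, an optional sinusoidal deformation
`r(theta) = R (1 + a cos(k (theta - phase)))` whose phase can twist
along the stack, and bright spherical markers placed at exact azimuth
and relative wall depth. Boundary contours are emitted analytically
(not re-segmented from the raster), so meshing accuracy is tested
independently of segmentation error. Additive Gaussian noise is seeded
and off by default, keeping every phantom bit-reproducible.

The bundled study conditions, fixed once: the deformed phantom is
512 x 512 x 61 with radii 100/180 px, amplitude 0.15, three lobes and a
quarter-turn twist, meshed on every 20th slice at `C = 5`; the marker
phantom is 256 x 256 x 21 with radii 50/90 px and twelve markers at
depths {0.25, 0.5, 0.75} and azimuths {0, 90, 180, 270} degrees, with
`C = 5` so the marker depths coincide with depth levels and the depth
tolerance is `1/(C-1) = 0.25`. These sizes keep a full verification run
in the low minutes on one CPU while exercising deformation, twist and
all four azimuthal quadrants.

What the phantoms do *not* emulate: CT physics (phase contrast, beam
hardening, rings), segmentation error in the boundary contours (they
are analytic), anisotropic voxels, and walls whose thickness varies
faster than the field-line window can follow. Passing the phantom suite
therefore validates the geometry pipeline, not boundary segmentation on
real data — boundaries are drawn by the user, per the method's design.

## A worked example

```{r example, eval = FALSE}
spec <- phantom_preset("marker-sheet")
ph <- make_tube(spec, key_interval = 10)
cfg <- run_config(m = 10, n_levels = 5)
surfaces <- mesh_sections(ph$contours, dim(ph$volume)[3], cfg)
cyclo <- probe_volume(ph$volume, surfaces)
cyclo
#> 3D cyclorama: L=565 x H=21 x C=5, origin (128.5, 128.5), bilinear probing, 0 out-of-bounds
reference_length(surfaces)        # round(2 * pi * 90) = 565
count_nesting_escapes(surfaces)   # 0: surfaces are properly nested
```

The panorama length 565 px equals the rounded perimeter of the outer
boundary (the longest contour), every one of the 21 x 5 contours is
nested inside its successor, and probing the markers back through the
stored source coordinates recovers their ground-truth azimuths to a
fraction of a degree and their depths exactly (see
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`).

## Known limitations

* Distances and areas are not preserved on panoramas; pixel size varies
  between rows and between depth levels. Measure in the original voxel
  grid (via the inverse map), never on the cyclorama.
* The method is slice-wise 2D by construction; strongly oblique tubes
  should be re-oriented to roughly vertical first.
* Very thin walls need `delta` smaller than the local thickness, or
  lines fail at the first step.
* The open-boundary sheet path (`make_c_shape()`,
  `trace_sheet_line()`) is experimental: it demonstrates that the
  field-line construction extends to non-closed boundaries but is not
  part of the supported tube pipeline.
* Alternative surface-to-plane mappings (isometric embedding, moving
  least squares) would trade the fixed panorama size for lower
  distortion; they are extension points, not implemented.
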