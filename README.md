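# cyclorama

Digital unrolling of deformed tubes of non-uniform wall thickness from
3D grey-value image stacks.

Tubular samples — intact colons imaged by micro-CT, tooth roots with
annual cementum layers, long-bone shafts, rolled pharmaceutical films —
hide their interesting features on curved shells inside a deformed
wall. Physically flattening such samples (e.g. the "Swiss roll"
preparation of a murine colon) destroys their 3D structure. `cyclorama`
unrolls them digitally instead: it meshes the wall of each cross
section with virtual electrostatic field lines, uses the line lengths
as the local wall thickness, builds nested onion-like re-slicing
surfaces at fixed relative depths, and maps every surface onto a planar
panorama. The panoramas all share the same size, so stacking them gives
a "3D cyclorama" in which a feature (say, a budding colonic crypt) can
be followed through tissue depth, and any annotation made on the
panoramas maps exactly back into the original voxel grid.

## The method in brief

On a cross section with inner boundary points `p_i` (charge +1) and
outer boundary points `p'_i` (charge −rigidity), `i = 0..I−1`, a field
line starts at `p_i` with a step `δ` along the inward boundary normal,
then repeats

    p_{i,k} = p_{i,k−1} + δ · E(p_{i,k−1}) / ‖E(p_{i,k−1})‖,
    E(p) = Σ_{j∈J} (p − p_j)/‖p − p_j‖³ − rigidity · Σ_{j∈J} (p − p'_j)/‖p − p'_j‖³,

with `J` a sliding window of `2w+1` indices around `i`, until it lands
on/beyond the outer boundary or `K_max` steps are spent. Lines that
fail to cross (stray) or stall near their start (scatter variance
`< V_min`) are discarded. The length `d_i` of a surviving line, clipped
at the outer polygon, is the local wall thickness; internal contours
are placed at absolute depths `c/(C−1) · d_i` along each line and
interpolated vertically across slices with cubic splines. Every contour
is opened at azimuth π about a rotation axis `O`, stretched to the
length `L` of the longest contour in the volume, and used to probe the
image — giving `C` panoramas of identical size `L × H` whose stored
source coordinates make the mapping invertible.

## Worked example

Everything below is synthetic — no data download is needed. The marker
phantom is a straight circular tube (wall radii 50–90 px, 21 slices)
carrying twelve bright markers at known azimuths and relative depths.

```r
library(cyclorama)

spec <- phantom_preset("marker-sheet")
ph   <- make_tube(spec, key_interval = 10)      # volume + analytic contours
cfg  <- run_config(m = 10, n_levels = 5)        # I=200, w=15, delta=2, ...
surf <- mesh_sections(ph$contours, dim(ph$volume)[3], cfg)
cy   <- probe_volume(ph$volume, surf)
cy
#> 3D cyclorama: L=565 x H=21 x C=5, origin (128.5, 128.5), bilinear probing, 0 out-of-bounds
reference_length(surf)
#> [1] 565
count_nesting_escapes(surf)
#> [1] 0
```

The panorama length 565 equals `round(2π · 90)`, the rounded perimeter
of the outer boundary — the longest contour in the volume — and none of
the 21 × 5 internal contours escapes its enclosing neighbour. The
markers reappear in the cyclorama exactly at their ground-truth depth
levels (depth error 0 at `C = 5`) and within a fraction of a degree of
their azimuths; a seed point marked on a panorama maps back to its
source voxel to sub-voxel accuracy, and dilating it with `cube = 5`
yields the 5 × 5 × 5-voxel seed volumes used to initialise
region-growing segmentation:

```r
mask <- inverse_map(cbind(l = 30, h = 11, c = 2), cy, cube = 5)
sum(mask)
#> [1] 125
```

From the shell, the same pipeline runs as

```sh
Rscript inst/cli/cyclorama.R phantom --preset concentric --seed 1 --out ph/
Rscript inst/cli/cyclorama.R unroll --stack ph/stack.tif --contours ph/contours.json \
    --points 200 --window 15 --delta 2 --vmin 50 --rigidity 1 \
    --interp-interval 20 --depth-levels 30 --kmax 75 --out cyclo
Rscript inst/cli/cyclorama.R invmap --sidecar cyclo_map.rds --points seeds.json \
    --cube 5 --out mask.tif
```

`unroll` accepts boundary contours either as the JSON dialect shown in
`ph/contours.json` or as an ImageJ ROI `.zip` archive (polygon ROIs
named `inner_*`/`outer_*`, slice taken from the ROI position field).

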