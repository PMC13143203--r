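# tastequant

Quantitative tools for taste biology: volumetric EdU proliferation
measurement in lingual-organoid confocal z-stacks, taste-bud profile
morphometry, rodent taste-behavior scoring (two-bottle preference and
brief-access lickometer), and relative qPCR quantification by the
ΔΔCt method — together with ground-truthed synthetic generators so
every stage is verifiable without microscope or animal data.

## Who this is for

Labs that image organoids (or comparable dense 3D tissue) in two
fluorescence channels — a DAPI nuclear channel and an EdU proliferation
channel — and want a reproducible, scriptable version of the standard
volumetric quantification, plus the bookkeeping around it: mask export,
per-organoid CSV reports, behavioral score sheets and qPCR fold
changes.

## The core algorithm

Nuclei inside an organoid are too tightly clustered to separate, so the
pipeline measures a **voxel-volume ratio**, not a cell count. Each
channel is processed independently:

1. min–max normalization to [0, 1] (segmentation becomes invariant to
   positive rescaling of raw intensities);
2. 3D median filter (3×3×3);
3. 3D Gaussian filter (5×5×5, σ = 0.5 voxel);
4. grayscale erosion with a discrete ball of radius 3 voxels → marker;
5. morphological reconstruction by dilation of the filtered volume
   under that marker (opening by reconstruction — removes bright
   structures smaller than the ball, restores nuclei exactly);
6. Otsu threshold on a 256-bin histogram, **scaled by a per-channel
   factor** (0.5 nuclear, 0.2 proliferation, identical for all
   stacks); voxels strictly above the scaled level are positive.

The proliferation readout is then

    ratio = (# EdU-positive voxels) / (# DAPI-positive voxels)

i.e. the fraction of total nuclear volume that is EdU-labeled. The
morphology and thresholding primitives are implemented in C++ and are
property-tested against naive brute-force R oracles (exact on integer
inputs).

Alongside the imaging pipeline: `max_projection()` and
`polygon_area()` (shoelace area of a freehand outline at a
pixels-per-µm scale) for taste-bud profile morphometry,
`categorize_marker_counts()` (fractions of organoids with 0, 1–9, ≥10
immunopositive cells), `per_mouse_average()` (mouse-level means, then
condition mean ± s.e.m. over mice), `two_bottle_preference()`,
`lick_ratio()`, `thirst_metric()` and `ddct_fold_change()`.

## Worked example

```r
library(tastequant)

# a ground-truthed synthetic organoid: 20 nuclei, 30% EdU-labeled
sim <- simulate_organoid_stack(shape = c(36, 72, 72), n_nuclei = 20,
                               nucleus_radius = 6, edu_fraction = 0.3,
                               seed = 42)
sim$stack
#> VolumeStack: 2 channel(s) [DAPI, EdU], 36 x 72 x 72 (z,y,x)
#>   source: simulate_organoid_stack(seed=42)

segment_channel(sim$stack, "DAPI", channel_params("nuclear"))
#> ChannelSegmentation 'DAPI': 20944 / 186624 voxels positive
#>   otsu level 0.4121 x factor 0.50 -> threshold 0.2061

rec <- quantify_stack(sim$stack, organoid_id = "demo")
rec[, c("organoid_id", "edu_positive_voxels", "dapi_positive_voxels",
        "edu_dapi_ratio")]
#>   organoid_id edu_positive_voxels dapi_positive_voxels edu_dapi_ratio
#> 1        demo                7805                20944      0.3726604
```

20,944 of 186,624 voxels are DAPI-positive and 7,805 of those
voxel-volumes are EdU-positive, giving a ratio of 0.373 against a true
label fraction of 0.30 — at this small nucleus radius the differing
per-channel thresholds cut the blurred nucleus edge at slightly
different radii, a partial-volume bias that shrinks as nuclei grow
relative to the point-spread blur (see the vignette; at the generator's
default radius of 12 voxels the recovered ratio is ≈ 0.34).

A behavior score, equally terse:

```r
two_bottle_preference(6.2, 3.1)   # ml tastant, ml water over 48 h
#> [1] 66.66667                    # >50 = preference for the tastant
```

Command-line use (`inst/cli/tastequant.R`) mirrors the same functions:

```sh
Rscript inst/cli/tastequant.R simulate --kind stack --seed 7 --out demo
Rscript inst/cli/tastequant.R quantify-edu --input demo.tif \
    --config config.yaml --out report.csv --save-masks masks/
```

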