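---
title: "Quantifying EdU proliferation in organoid z-stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying EdU proliferation in organoid z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(tastequant)
```

## The measurement problem

Lingual organoids are dense balls of cells grown from taste progenitors.
Proliferation is read out by pulsing cultures with EdU, a thymidine
analogue incorporated during S phase, and imaging fixed organoids as
confocal z-stacks with a DAPI channel (all nuclei) and an EdU channel
(nuclei that replicated DNA during the pulse). Nuclei inside an organoid
are packed too tightly for reliable instance segmentation, so the
package deliberately does not count cells. Instead it measures a volume
ratio:

$$
\mathrm{ratio} \;=\;
\frac{\#\{\text{EdU}^+\ \text{voxels}\}}{\#\{\text{DAPI}^+\ \text{voxels}\}},
$$

the fraction of total nuclear volume that is EdU-labeled. When nuclei
have comparable volumes this tracks the fraction of proliferating
cells; when they do not, it is still a well-defined proliferation index
but should not be read as a cell fraction.

## The segmentation chain

Each channel is processed independently (`segment_channel()`), in this
fixed order:

1. **Min–max normalization** (`normalize_stack()`): voxel intensities
   are mapped to $[0,1]$ by $(v - \min)/(\max - \min)$. Segmentation is
   therefore invariant to any positive affine rescaling of the raw
   counts — 8-bit, 12-bit and 16-bit exports of the same field give
   identical masks. A constant channel maps to all zeros rather than
   erroring, so an all-blank channel flows through to an empty mask.
2. **3D median filter** (`median_filter_3d()`, window 3): removes
   shot-noise speckle while preserving nuclear edges.
3. **3D Gaussian filter** (`gaussian_filter_3d()`, 5×5×5 kernel,
   $\sigma = 0.5$ voxel): light smoothing; the kernel is truncated to
   the stated size and renormalized to sum 1 so constant regions are
   preserved.
4. **Erosion** (`erode_3d()`) with a discrete ball of radius 3 voxels
   (`ball_element(3)`, 123 offsets) to form a *marker*.
5. **Morphological reconstruction by dilation**
   (`reconstruct_by_dilation()`) of the filtered volume under that
   marker — grayscale opening by reconstruction. Bright structures too
   small to contain the ball (noise, debris) are flattened; nuclei are
   restored to their filtered values exactly.
6. **Scaled Otsu threshold**: an Otsu level is computed on a 256-bin
   histogram of the reconstructed volume (`otsu_threshold()`) and
   multiplied by a per-channel factor — 0.5 for the nuclear channel,
   0.2 for the proliferation channel. The same factors are applied to
   every stack. A voxel is positive iff its value is *strictly greater*
   than the scaled level (`binarize()`).

`quantify_stack()` runs the chain on both channels and reports the
ratio with voxel tallies and a full parameter snapshot, one row per
organoid (multi-organoid fields should be cropped first, so that the
ratio is per organoid).

## Numerical conventions

These details pin down behavior the one-line description leaves open;
all of them are exercised by oracle tests against naive brute-force
implementations.

* **Histogramming.** Values in $[0,1]$ fall into 256 equal-width bins
  (value 1.0 is clamped into the top bin). Candidate thresholds are the
  255 interior bin boundaries $k/256$; the between-class variance is
  maximized by exhaustive search.
* **Otsu ties.** When several boundaries tie (e.g. an empty gap between
  two clusters), the *mean* of the tying boundaries is returned. This
  is deterministic and symmetric: a 50/50 mix of values 0 and 1 yields
  exactly 0.5.
* **Degenerate channels.** A constant volume gets Otsu level 0; with
  any positive factor and the strict inequality, an all-zero channel
  produces an empty mask and ratio 0.
* **Boundary padding.** Both linear filters use symmetric
  (edge-inclusive) reflection, so the volume rim is not artificially
  darkened before thresholding. Erosion instead *ignores* out-of-bounds
  offsets (treats them as $+\infty$), the standard flat-erosion
  convention on a finite domain.
* **Reconstruction connectivity** defaults to 26 (full 3D
  neighborhood); 6 and 18 are selectable. The implementation is
  Vincent's hybrid algorithm (two raster scans plus a FIFO queue) and
  is property-tested against the naive iterate-until-stable fixed
  point.
* **Threshold source.** The Otsu level is computed on, and the
  binarization applied to, the reconstructed volume by default; a
  `threshold_source = "filtered"` switch uses the pre-erosion filtered
  volume instead, for sensitivity analyses. The reconstructed volume is
  the default because it is the last processing product before
  segmentation in the chain.
* **Marker/mask roles are fixed**: the marker is always the eroded
  filtered volume and the mask the filtered volume. This is the
  contrast-enhancement step and is not configurable.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `otsu_factor` (nuclear) | 0.5 | — | fixed constant of the method; same for all stacks |
| `otsu_factor` (proliferation) | 0.2 | — | fixed constant of the method; EdU signal is dimmer and sparser |
| `median_window` | 3 | voxels | the standard default 3×3×3 neighborhood |
| `gaussian_kernel` | 5 | voxels | stated filter size |
| `gaussian_sigma` | 0.5 | voxels | default of the invoked function family; recorded in every report row |
| `erosion_radius` | 3 | voxels | stated ball radius |
| `connectivity` | 26 | — | default neighborhood of the invoked reconstruction |

The two factors and the structural sizes are treated as constants of
the method; the sigma and connectivity are conventions documented here
because the method description does not pin them down. Filtering
operates in voxel units throughout — anisotropic physical-unit
filtering is out of scope, and voxel size is carried only as metadata.

## What the synthetic generator emulates

`simulate_organoid_stack()` builds ground-truthed two-channel stacks:
`n_nuclei` non-overlapping hard spheres of equal radius packed
uniformly at random (rejection sampling), rendered at unit amplitude
into the DAPI channel; an exact-count random subset is rendered
identically into the EdU channel; both channels are blurred with a
Gaussian PSF, offset by a background level and corrupted with additive
Gaussian noise of sd $(\text{amplitude}-\text{background})/\mathrm{snr}$,
then clipped at zero. Hard spheres, not soft blobs, so that the
ground-truth voxel volume — and hence the expected ratio — is
unambiguous: with equal radii the true volume ratio equals the labeled
fraction exactly.

The defaults describe a specific, realistic imaging regime: a field of
72×176×176 voxels at roughly 0.33 µm/voxel holding 60 nuclei of radius
12 voxels (≈ 4 µm, a typical epithelial nucleus at high-NA sampling),
PSF sigma 0.5 voxel (sub-voxel, as for a confocal at this sampling),
background 2% of signal and SNR 50. Two of these choices matter more
than they look:

* **Nuclei must be large relative to the PSF.** The two channels are
  thresholded at different scaled levels (0.5 vs 0.2 of their Otsu
  levels), which cut the blurred nucleus edge at different
  iso-intensity radii. Each mask is a sphere of radius $R+\delta$ with
  a channel-specific $\delta$ of a fraction of the edge width, so the
  measured ratio is inflated by $((R+\delta_E)/(R+\delta_D))^3$ — a
  surface effect that decays like $1/R$. At the default radius this
  partial-volume bias is a few percent of the label fraction; with
  small nuclei (radius ≲ 5 voxels at this PSF) it can exceed 20% and
  the voxel ratio stops being a good estimate of the cell fraction.
  The same caveat applies to real data and is inherent in using
  different factors per channel.
* **Background must sit below the proliferation threshold.** The EdU
  mask is cut at 0.2 × Otsu level; if the normalized background
  approaches that value, background voxels flood the mask. Dark
  backgrounds (a few percent of signal) keep the method in its working
  regime.

What the generator does **not** emulate: anisotropic axial PSF (real
2 µm optical sections are coarser in z), organoid lumen/shell geometry,
intensity heterogeneity within and between nuclei, photobleaching, and
autofluorescent debris. Passing recovery tests on these stacks
therefore shows the *algorithm* is implemented and behaves as designed
in its working regime — not that the ratio is unbiased on arbitrary
real acquisitions.

A known limitation worth stating plainly: a channel containing **noise
but no signal** is over-segmented. Min–max normalization stretches pure
noise across $[0,1]$ and Otsu then splits the noise distribution, so a
noise-only EdU channel yields a large spurious mask. The original
workflow guarded this with visual inspection of every segmentation;
users of this package should do the same, or check the reported
effective thresholds against their background level. Only a truly
signal-free (constant) channel degrades gracefully to an empty mask.

## Behavioral and qPCR scores

* `two_bottle_preference()`: $100 \cdot t/(t+w)$ over the 48 h test
  (sides swapped at 24 h upstream); 50 is the no-preference line, and
  the complementarity $p(t,w) + p(w,t) = 100$ is tested.
* `lick_ratio()`: mean licks across eligible tastant trials at one
  concentration divided by mean licks across eligible water trials,
  *pooled* over the two testing days. Pooling-then-dividing is the
  default reading of averaging across days; a per-day-ratio-then-mean
  variant sits behind `per_day = TRUE` for comparison. First-block
  exclusion (`exclude_first_block = TRUE`) is the convention for the
  sweet panel, where first-block licking reflects thirst rather than
  taste; it is off by default and should be switched on per panel.
* `thirst_metric()`: total first-block licks averaged across testing
  days — the motivational-state control.
* `ddct_fold_change()`: per-sample $\Delta Ct$ against the housekeeping
  gene (default *Rpl19*), centered on the *arithmetic mean* of the
  control-group $\Delta Ct$ (the method's standard convention), folds as
  $2^{-\Delta\Delta Ct}$. A consequence used as a test invariant: the
  geometric mean of control folds is exactly 1, and any Ct offset
  shared by all wells cancels. Replicate-well collapsing is left to the
  caller, which takes one Ct per sample and gene.

## Problem sizes used by the test suite

Oracle-equivalence tests run the compiled primitives against plain-R
brute-force implementations on one hundred seeded random volumes of up
to 8×8×8 voxels per primitive (exact agreement on integer-valued input,
1e-9 on floats — the brute-force oracles share no code with the
implementation). End-to-end recovery uses ten seeds of the default
generator (60 nuclei, 30% labeled), requiring the measured ratio within
±0.05 of 0.3 in at least nine; unit tests use smaller fields (4–20
nuclei, radius 4–6) chosen so the whole suite runs in a couple of
minutes on one core. These sizes are the package's chosen verification
scale; the pipeline itself has no size limit beyond memory.

## Known limitations

* No instance segmentation: touching nuclei are never separated, which
  is why the output is a volume ratio.
* Voxel-unit filtering; anisotropy is the caller's responsibility
  (e.g. resample before segmentation if z-steps are coarse).
* Noise-only channels over-segment (see above).
* Exact numerical parity with any other implementation of the chain is
  not claimed at volume borders: padding behavior is documented here
  but is a convention, not a published fact.
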