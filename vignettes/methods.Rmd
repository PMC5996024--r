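---
title: "Methods: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centripatch)
```

`centripatch` quantifies the apical surface of multiciliated ependymal
cells: how many centrioles a cell carries, how they are arranged into a
patch, which way the basal bodies point, how the actin cytoskeleton is
enriched over the patch, how the cilia beat, and what mechanical load the
beat places on each centriole.  This vignette explains the underlying
models, every default parameter, and the numerical decisions, so that the
results can be audited without reading the source.

## The synthetic scene generator

Real validation data with voxel-exact ground truth do not exist, so the
package ships a generator whose scenes are the reference standard for every
other module.  `scene_spec()` describes a field of cells; `render_stack()`
turns it into a four-channel 3D stack (`centrin`, `cep164`, `actin`,
`membrane`) plus exact ground truth.

**Layout.** Cells are rectangles tiling a near-square grid, each
`cell_size_um = 6.4` µm across — the scale of a mature ependymal apical
domain.  Rectangles keep point-in-cell assignment unambiguous and make the
border masks exact; real cells are irregular polygons, which affects only
the edge cases of spot-to-cell assignment, not the per-cell statistics.

**Centrioles.** Each cell receives `centrioles_per_cell = 30` centrin
puncta — the count scale of a mature cell — placed by dart throwing inside
a disc of `patch_radius_um = 1.8` µm with a hard minimum spacing of
`min_spacing_um = 0.4` µm, emulating the crowded but non-overlapping
packing of basal bodies.  A feasibility guard (70 % of the hexagonal
packing bound) fails loudly before attempting an impossible placement.
The patch centre is displaced `patch_offset_um = 1.1` µm from the cell
centre *along the cell's beat direction*, reproducing the anterior
asymmetry of patch position, so patch displacement and beat orientation are
correlated in the ground truth just as they are in tissue.

**Orientation.** Each cell draws a mean beat direction (uniform on the
circle unless fixed), and each centriole draws its own direction from a von
Mises distribution around that mean with `orientation_kappa = 4` — tight
enough that a cell is clearly polarised, loose enough that per-centriole
scatter is visible.  The distal-appendage marker punctum (Cep164) is
displaced `cep164_offset_um = 0.25` µm from its centrin partner along that
direction; the centrin-to-Cep164 vector therefore *is* the basal-body
orientation, which is exactly how orientation is read in real images.

**Optics and noise.** Puncta are rendered as 3D Gaussians of
`psf_sigma_um = (0.1, 0.1, 0.25)` µm — a confocal-like point-spread
function, broader axially — on a voxel grid of
`voxel_size_um = (0.1, 0.1, 0.23)` µm with `n_z = 14` planes.  Noise is
applied shot-noise-first (Poisson at an optional scale) then Gaussian read
noise of `noise_sd`; with the default `peak_intensity = 100`,
`noise_sd = 20` gives a peak signal-to-noise ratio of 5, the regime in
which the detector is validated.  All randomness derives from one integer
`seed`, so identical specs give bit-identical stacks.

**Actin.** The actin channel is two thin sheets: an apical one at the
Cep164 plane (60 % of stack depth by default) and a subapical one
`subapical_drop_um = 0.92` µm deeper (four z-steps, so the two 6-plane
measurement bands cannot share a plane).  Within a sheet the rest of the
cell has intensity 1 and the patch carries the target ratio
(`actin_ratio_apical = 2`, `actin_ratio_subapical = 1.5`), so the
patch/rest ratio of a band projection recovers the target *exactly* in the
noiseless case — the generator is deliberately constructed so that the
quantification has a closed-form right answer.

Known simplifications: rectangular cells, isotropic xy PSF, sheet-like
actin (real actin fills a volume), and no z-drift or bleaching.  These are
acceptable because every downstream claim is about recovering parameters
the generator controls, not about photorealism.

## Detection and counting

Stacks are smoothed with a separable 3D Gaussian and filtered with a
sign-flipped Laplacian of Gaussian (`filter_stack()`); both take sigmas in
physical units (`0.1, 0.1, 0.25` µm, matched to the PSF) and convert to
voxels per axis, so anisotropic sampling is handled correctly.
Second-derivative kernels are explicitly zero-summed so a constant
background yields exactly zero response.  Convolution replicates edge
values rather than wrapping, as the biology does not continue across the
stack border.

`extract_maxima()` takes local maxima over a box neighbourhood of
`min_distance_um = 0.3` µm (about the resolvable centriole spacing),
thresholds at the `0.995` intensity quantile of the filtered response, and
applies greedy Euclidean minimum-distance suppression in physical
coordinates.  The convention throughout is that voxel *i* is centred at
(i − 0.5)·Δ µm.  Optional quadratic sub-voxel refinement exists but is off
by default: at these voxel sizes the half-voxel quantisation error
(≤ 0.067 µm in xy) is far below the 0.3 µm matching radius, and discrete
positions are easier to reason about.

`count_centrioles()` assigns each spot to a cell polygon by ray casting; a
spot exactly on a shared edge is assigned to the lowest adjacent cell id,
deterministically, and overlapping polygons are an error rather than a
silent double count.

## Patch geometry

Per cell, `build_patch_model()` reports the number of detected centrioles,
the convex-hull area of the patch (`grDevices::chull` plus the shoelace
formula), and nearest-neighbour spacings in the xy plane (centrioles live
at one apical depth, so spacing is a 2D quantity).  A density rule —
`min_density = 3` neighbours within `density_radius_um` — separates the
patch from stray detections before the hull is taken, since a convex hull
is unboundedly sensitive to a single outlier.

## Basal-body orientation

Detected centrin and Cep164 spots of one cell are paired by minimising the
summed xy distance over all pairings — a rectangular assignment problem
solved exactly by a Jonker–Volgenant shortest-augmenting-path algorithm in
O(n²m) (`solve_assignment()`); no installed package provided this, so it is
implemented here and verified against exhaustive enumeration in the test
suite.  Greedy nearest-neighbour pairing fails visibly in crowded patches,
which is why exact assignment is worth the implementation cost.  Unequal
set sizes produce `min(n, m)` pairs and an explicit list of unmatched
spots.

Per-pair angles feed standard circular statistics
(`orientation_stats()`): mean direction from the resultant vector,
resultant length `R`, a von Mises concentration estimate `kappa_from_R()`
(the usual three-regime approximation), and the circular standard error
`1/sqrt(n R kappa)`.  The rose-plot histogram uses eighteen 20° half-open
bins, with a small epsilon guard so that angles landing exactly on a bin
edge on the degree grid bin deterministically.

Two orientation samples are compared with the two-sample Watson U² test —
chosen because it is invariant to a common rotation of both samples, which
a linear Kolmogorov–Smirnov test is not.  Ties are handled by collapsing
tie groups of the pooled sample; the p-value uses the standard asymptotic
series `P(U² > u) = 2 Σ (−1)^(j−1) exp(−2 j² π² u)` truncated at 100 terms,
with the exact limit p = 1 as u → 0.  The test's size (~5 % at n = m = 50)
is verified by simulation in the acceptance suite rather than assumed.

## Intensity quantification

`band_projection()` sums six z-planes (+3/−2 around the anchor plane, the
anchor being the plane whose centre is nearest the requested depth) and
`patch_ratio()` divides the mean projected intensity over the patch mask by
the mean over the rest of the cell, borders excluded.  Cell borders are
excluded from both masks because membrane-adjacent actin would otherwise
contaminate the "rest" denominator.

Group comparisons use rank tests (Mann–Whitney, Kruskal–Wallis with a
tie-corrected Dunn post hoc) because intensity ratios and counts are not
normal; outliers can be removed beforehand by a robust-regression-style
rule (median/MAD z-scores, t p-values, Benjamini–Hochberg at a chosen Q) —
implemented here because no installed package provides it.  Count drift
across ordered bins uses `stats::prop.trend.test`; treated-to-reference
count ratios are summarised by `fold_change_counts()` against a
contralateral, surrounding-tissue, or littermate reference.

## Beat kinetics

`beat_frequency()` mirrors manual cycle counting: linearly detrend the
trace, count peaks whose prominence exceeds 3× a robust noise SD estimated
from second differences (`mad(diff(x, 2))/sqrt(6)` — second differencing
annihilates slow trends and inflates white noise by √6), and divide by the
duration.  A periodogram cross-check reports the dominant spectral
frequency; disagreement beyond one frequency bin (`1/duration`, the
spectral resolution floor) flags the estimate instead of silently averaging
two inconsistent numbers.  A tiny absolute prominence floor
(`1e-8 × max(1, max|x|)`) prevents counting numerical ripple on
near-constant traces as beats.  Traces are sampled at 250 fps for 1 s by
default, giving a 1 Hz resolution floor against beat frequencies of a few
tens of Hz.

`beat_amplitude()` is the peak-to-peak tip excursion — twice the
half-amplitude of a sinusoidal beat.  `make_kymograph()` samples each frame
along a polyline at unit pixel spacing with bilinear interpolation over a
200 ms default window, the classic position×time readout of periodicity.

The synthetic trace generator rescales its sampled waveform to exactly
[−A, A] so that the peak-to-peak ground truth is exactly 2A even when the
sampling grid is incommensurate with the beat period.

## The force model

A beating cilium is modelled as a slender rigid cylinder of radius
`r = 99` nm and length `L = 11.1` µm in fluid of viscosity
`µ = 1e-3` N·s·m⁻², with resistive drag coefficient

> C = 4πµ / log₁₀(L/r) ≈ 6.13 × 10⁻³ N·s·m⁻²,

the base-10 logarithm being the package's deliberate convention (the base
is an argument of `drag_coefficient()`; natural log gives 2.7 × 10⁻³).
The time-averaged force the fluid exerts on the cilium is
`F_flow = C f A L` for beat frequency `f` and amplitude `A`.  Because the
cilium is anchored over a lever arm of only `Lc = 510` nm (the
centriole/rootlet length) while the drag acts over the full length, the
load at the anchor is amplified by `L/Lc ≈ 21.8`:
`F_torque = F_flow · L/Lc`.  Note that C *increases* with radius — a
thicker cylinder drags more; the log shrinks as `L/r` falls.
`sensitivity_table()` tabulates both forces over ranges of any geometric
parameter, and `parse_length()` accepts unit-suffixed strings ("99nm",
"11.1um").

The default beat amplitude of 5 µm used in examples is an assumption of
convenient magnitude, not a measured constant; amplitude enters all forces
linearly, so results rescale trivially.

## Validation design

The acceptance tests (`tests/testthat/test-acceptance.R`) pin each module
to an independent reference: assignment and geometry against brute-force
oracles; detection against ground truth at SNR 5 (recall and precision
≥ 0.95 at a 0.3 µm radius over ten seeds); orientation recovery within
three circular standard errors on at least 49 of 50 cells (three SE is
~99.7 % coverage, so demanding all 50 would fail a perfect estimator about
one run in seven); Watson U² size in [0.03, 0.08] and power ≥ 0.9 against a
quarter-turn shift; exact recovery of actin ratios, beat frequency, and
peak-to-peak amplitude on noiseless scenes; and a simulated 40 % ablation
reading out as a 0.6 fold change.  Problem sizes (≤ 7 points for the
factorial oracle, 50-cell fields, 500 null replicates) were chosen to keep
the whole suite under a minute while leaving the statistical assertions
well-powered.
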