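# centripatch

Quantification of centriolar patches, basal-body orientation, actin
enrichment, and cilia beating in multiciliated ependymal cells — with a
synthetic-scene generator that provides exact ground truth for every step.

## The science

Ependymal cells lining the brain ventricles each grow dozens of motile
cilia whose coordinated beat drives cerebrospinal-fluid flow.  Each cilium
is anchored by a centriole (basal body); the centrioles cluster into a
single **patch** on the apical surface, displaced towards the downstream
side of the cell, and each basal body carries a distal appendage (marked by
Cep164) pointing in its beat direction.  An actin network enriched over the
patch at two z-levels anchors the centrioles against the mechanical load of
beating.  This package measures all of these readouts from 3D fluorescence
stacks and high-speed recordings:

- **Detection/counting** — separable 3D Gaussian + Laplacian-of-Gaussian
  filtering, local-maximum extraction with minimum-distance suppression,
  and point-in-polygon assignment of spots to cells.
- **Patch geometry** — convex-hull area, nearest-neighbour spacing, and a
  density-based patch boundary robust to stray detections.
- **Orientation** — exact minimum-cost pairing of centrin with Cep164
  puncta (Jonker–Volgenant assignment), circular mean/resultant
  length/concentration, circular standard errors, 20°-bin rose histograms,
  and the rotation-invariant two-sample Watson U² test.
- **Intensity** — patch/rest actin ratios on 6-plane band projections at
  apical and subapical depths, rank tests with Dunn post hoc, outlier
  removal by FDR-controlled robust z-scores, and fold-change summaries.
- **Kinetics** — beat frequency by prominence-gated peak counting with a
  periodogram cross-check, peak-to-peak amplitude, and kymographs from
  250-fps movies.
- **Forces** — a slender-cylinder drag model: C = 4πµ/log₁₀(L/r), the
  time-averaged flow force F = C·f·A·L, and its amplification at the short
  centriolar anchor, F_torque = F · L/L_c.

The methods vignette (`vignettes/methods.Rmd`) documents every model,
default parameter, and numerical choice.

## Worked example

```r
library(centripatch)

# a 4-cell synthetic field with exact ground truth
sp  <- scene_spec(n_cells = 4, seed = 7)
tbl <- run_image_pipeline(sp)
tbl[, c("cell_id", "count", "patch_area_um2", "mean_nn_um",
        "mean_direction_rad", "R", "apical_ratio", "subapical_ratio")]
#>   cell_id count patch_area_um2 mean_nn_um mean_direction_rad     R apical_ratio subapical_ratio
#> 1       1    30           7.98      0.486             -2.956 0.863            2             1.5
#> 2       2    30           7.62      0.468             -0.983 0.831            2             1.5
#> 3       3    30           8.02      0.489              0.171 0.897            2             1.5
#> 4       4    30           7.97      0.482             -0.866 0.848            2             1.5

# ground-truth beat directions for comparison (radians, wrapped to (-pi, pi]):
sample_ground_truth(sp)$cells$mean_direction_rad
#> [1]  3.072 -0.890  0.301 -0.976
```

All 30 centrioles per cell are recovered, actin ratios are exact on a
noiseless scene, and each estimated direction sits within its circular
standard error of the truth (cell 1's −2.956 and 3.072 differ by 0.26 rad
across the ±π wrap).

```r
# beat kinetics from a noisy 250-fps trace, fed into the force model
tr <- render_trace(beat_spec(frequency = 28, amplitude = 5,
                             noise_sd = 0.2, seed = 2))
bf <- beat_frequency(tr)     # bf$frequency_hz = 28, spectral check = 28
ba <- beat_amplitude(tr, 28) # ba$amplitude_um = 10.68 (peak-to-peak)

g <- cilia_geometry(f_hz = bf$frequency_hz, A_m = ba$amplitude_um / 2 * 1e-6)
drag_coefficient(g)                      #> 0.00613 N s m^-2
flow_force(g) * 1e12                     #> 10.2 pN on the cilium
torque_force(g, flow_force(g)) * 1e12    #> 221 pN at the centriole
```

The ~22× amplification from cilium to centriole (L/L_c = 11.1 µm/510 nm)
is why patch-anchoring actin matters.

```r
# are two cells' orientation fields different?  Watson U2, rotation-invariant
a <- rvonmises(50, 0, 4); b <- rvonmises(50, pi / 2, 4)
watson_u2_test(a, b)
#> $statistic 1.8   $p_value 7.4e-16
```

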