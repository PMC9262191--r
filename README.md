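# mitotraj

Single-cell analysis of mitotic progression in 2D+t fluorescence microscopy.

`mitotraj` turns time-lapse movies of chromatin-labelled nuclei (e.g. HeLa
H2B-mCherry, one frame every few minutes) into synchronized single-cell
mitotic trajectories and quantitative readouts, for cell biologists studying
mitosis and mitotic exit under different treatments (RNAi screens, drug
panels) and for image analysts who need a scriptable, fully offline-testable
pipeline.

## What it computes

For every cell division found in a movie, the package extracts a fixed
window of frames around the division (defaults: 30 before, 60 after — 90 and
180 minutes at 3-minute sampling) and synchronizes it on two anchors:

* **IP** — interphase→prophase transition (first frame of chromatin
  condensation, state 1→2),
* **MA** — anaphase onset (first frame of separated sister chromatin masses,
  state 2→3),

so that per-frame states form the monotone sequence 1…1 2…2 3…3 (or all 0
for a rejected track). The stages:

1. **Detection** — multi-scale Laplacian-of-Gaussian filtering; centroids are
   local maxima of the scale-normalized response −σ²∇²G ∗ I.
2. **Tracking** — time-reversed linking via Ward-linkage hierarchical
   clustering of consecutive-frame centroids, cut at half the mean 8-nearest-
   neighbour distance; two tracks meeting one predecessor annotate a
   division.
3. **Segmentation** — per-detection patch, 5×5 median filter, binarization at
   `(T_Otsu + min_center)/2`, and a two-seed watershed (patch centre vs.
   border) on the inverted Euclidean distance map; optional merge with
   external instance-segmentation labels (central label kept, classical
   fallback flagged).
4. **Features** — area, axes, axial orientation, circularity
   `4π·area/perimeter²`, intensity statistics; 13 Haralick statistics from
   64-level co-occurrence matrices (background transitions removed, offsets
   (0,1),(1,0),(1,1),(−1,1), averaged); spindle-channel statistics on
   dilated/eroded/toroidal masks (disk radius 15 px) including the
   intensity-maximum displacement; sister-centroid distance and
   metaphase-plate rotation angles.
5. **Synchronization** — IP via temporally constrained 2-cluster splitting
   (TC3: exhaustive within-class-variance minimization over contiguous
   splits) of (area, circularity, mean intensity, intensity s.d.); MA via the
   first sister-distance threshold crossing; or HMM/Viterbi decoding of any
   per-frame state-probability table; or manual CSV annotations.
6. **Derived features & statistics** — smoothing, normalization to the
   interphase mean or first late-anaphase value, windowed regression slopes,
   and the interphase-recovery series
   `R(t) = 100 − mean_f min(100, |v_f(t) − μ_f|/μ_f · 100)` (100% = fully
   recovered); selection by metadata/feature ranges; t/ANOVA/Wilcoxon/
   Kruskal–Wallis and two-way treatment×time ANOVA; fold-change feature
   ranking with an HTML report; aligned heatmap/mean±sd/violin/box/histogram
   plots.

A synthetic mitotic-movie generator (`sim_params()` / `generate_movie()`)
renders all of these dynamics with complete ground truth, so the entire
pipeline is testable without microscope data.

## Worked example

```r
library(mitotraj)

params <- sim_params(image_size = c(300, 300), n_cells = 4,
                     division_schedule = data.frame(cell_id = 1,
                                                    division_frame = 45),
                     n_frames = 110, seed = 42)
sim <- generate_movie(params)
sim$movie
#> movie_stack: 300 x 300 px, 110 frames, 2 channel(s) [chromatin, second]
#>   pixel size 0.65 um/px, interval 3 min/frame
#>   metadata: microscope=synthetic, experiment_id=sim, plate=1, position=1, treatment=none

project <- run_pipeline(sim$movie)
project
#> cell_project: 2 cell(s), window 90 frames, 35 time-series features, 7 single features
#>   synchronized: 2/2

cell <- project$cells[["d001_a"]]
cell$sync
#> sync_states: 90 frames, IP at 19, MA at 31
cat(sprintf("IP-to-MA duration: %.0f min\n", cell$single[["ip_ma_duration_min"]]))
#> IP-to-MA duration: 36 min
cat(sprintf("recovery at +180 min: %.1f %%\n", cell$ts[90, "derived/recovery"]))
#> recovery at +180 min: 93.1 %

fc <- fold_change_report(project)
fc[fc$feature %in% c("area", "minor_axis", "mean_int", "har_entropy"),
   c("feature", "mean", "fold_ip", "fold_ma")]
#>        feature   mean fold_ip fold_ma
#> 3         area  95.25   0.337   0.192
#> 16  minor_axis   9.77   0.592   0.448
#> 18    mean_int 115.15   1.861   1.904
#> 25 har_entropy   7.27   0.813   0.695
```

Reading the numbers: the one scheduled division is found at frame 45 and
both daughters are synchronized — IP at trajectory frame 19 and MA at 31,
i.e. 36 minutes of prophase-to-metaphase, matching the generator's 12-frame
condensation lead. Mean intensity rises 1.86-fold at prophase (the generator
condenses chromatin with a 1.8× intensity gain) while area drops to 0.34 of
interphase (configured shrink 0.6² = 0.36); by the end of the 180-minute
post-division window the recovery feature is back to 93% of interphase.

A thin command-line interface over the same functions lives at
`inst/cli/mitotraj.R` (`simulate`, `analyze`, `export`, `report`
subcommands).

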