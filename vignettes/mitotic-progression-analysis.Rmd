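---
title: "Quantifying mitotic progression from 2D+t chromatin movies"
author: "mitotraj authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitotic progression from 2D+t chromatin movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

Time-lapse fluorescence microscopy of chromatin-labelled cells (e.g. HeLa
expressing H2B-mCherry, imaged every 3 minutes at 0.65 um/px) records
hundreds of cells passing through mitosis. Comparing treatments requires
turning each movie into a set of *single-cell mitotic trajectories* — a fixed
window of frames around each division — whose feature time series are
*synchronized* on two biological anchors before they can be averaged:

* **IP**, the interphase-to-prophase transition: the first frame of visible
  chromatin condensation (state 1 to 2), and
* **MA**, anaphase onset: the first frame with clearly separated sister
  chromatin masses (state 2 to 3).

Because the duration of prophase through metaphase varies from cell to cell,
raw frame indices are not comparable; every readout in this package is
anchored on IP and MA. Per-frame states take values 0 (invalid track),
1 (interphase), 2 (prophase through early anaphase) and 3 (late
anaphase/telophase), and a valid track is always a monotone block sequence
1...1 2...2 3...3.

## Pipeline stages and their assumptions

**Detection.** Nuclei are bright, roughly elliptical blobs, so centroids are
local maxima of the scale-normalized negated Laplacian-of-Gaussian response.
The scale grid is derived from the expected nucleus diameter `d` as
`sigma = d / (2 sqrt(2) * pixel_size)` (the response of a solid disk of
radius `r` peaks at `sigma = r/sqrt(2)`). `make_resolution_preset()` spans
±40% around that centre; the movie-level default (`detect_movie()`) extends
the lower end to 0.35x because condensed chromatin and freshly separated
sisters are roughly half the interphase diameter and must not be missed —
losing them breaks tracks exactly at the division the analysis needs.
The detection threshold is relative to the per-frame maximum response
(default 0.1), which makes detection invariant to global intensity scaling
across microscopes; maxima closer than `sigma*sqrt(2)` (larger scale of the
pair) merge into the stronger one, which removes the large-scale maximum
that otherwise appears between a freshly separated sister pair.

**Tracking.** Cells move little between frames relative to their spacing, so
linking is done backward in time: the union of current- and next-frame
centroids is clustered by Ward-linkage agglomeration cut at a distance
threshold, and within a cluster each later detection links to its nearest
earlier one. The cutoff is half the average distance of each object to its
eight nearest neighbours (with `min(8, n-1)` neighbours in sparse frames —
the heuristic presumes dense fields). Two different tracks claiming the same
predecessor annotate a division at the *first frame where two daughters
exist* (early anaphase); clusters with more than two claimants are rejected
rather than split, since the model is strictly binary division. Tracking has
no randomness; Ward merges are resolved deterministically by `hclust`.

**Trajectory extraction.** A division is kept only if its parent track is
complete for `n_before = 30` frames and both daughters for `n_after = 60`
frames; windows are trimmed to exactly those lengths. At the 3-minute
default interval that is 90 minutes of interphase/early mitosis and 180
minutes of mitotic exit. Both daughters share the identical pre-division
segment.

**Segmentation.** Each detection is cropped to a square patch (96 px at
0.65 um/px, scaled inversely with pixel size so the field of view is
physically constant), median filtered (5x5), and binarized at the mean of
the 256-bin Otsu threshold and the minimum filtered intensity in the central
square covering half the patch side. Lowering Otsu's threshold this way
keeps a dim central cell that would otherwise be thresholded away next to a
brighter neighbour; because both terms scale with intensity, the mask is
invariant to global intensity scaling. A seeded watershed with exactly two
seeds — the patch centre and the border ring — runs on the inverted
Euclidean distance map (compiled Meyer flooding, 4-connected, deterministic
FIFO tie-breaks), and the centre region intersected with the binarization,
hole-filled, is the central-cell mask. The two-seed topology separates the
centre cell from neighbours across a background gap; cells *touching* the
centre cell are the job of the optional external instance segmentation,
whose labels are merged by keeping the instance at (or within 5 px of) the
patch centre, with the classical mask and a flag as fallback wherever no
label is present.

**Features.** Classical region features come from the mask's second central
moments (with the 1/12 pixel-variance correction) — area, centroid, axis
lengths, axial orientation in [-90, 90) — plus circularity
`4*pi*area/perimeter^2` with a chain-code perimeter using the
Vossepoel–Smeulders step weights (0.948/1.340), chosen so a rasterized disk
scores close to 1 instead of the ~1.12 a raw pixel-centre polygon gives.
Haralick texture features use 64-level co-occurrence matrices quantized over
the per-patch min–max range (texture therefore invariant to linear intensity
scaling across platforms), pairs restricted to mask-interior pixels
(background transitions removed), the offset set (0,1), (1,0), (1,1),
(-1,1), and the 13 primary statistics averaged over the offsets. The
unstable 14th statistic (maximal correlation coefficient) is deliberately
omitted. Entropies are reported in bits; the two information measures of
correlation keep their canonical natural-log form. Second-channel (spindle)
features are computed on the chromatin mask dilated and eroded by a
15-px-radius disk and on their difference (the toroidal ring), including the
displacement of the intensity maximum from the chromatin centroid, which
tracks astral/polar signal.

**Synchronization.** The default, classifier-free pathway anchors IP by
temporally constrained 2-cluster splitting (TC3) of the z-scored quadruple
(area, circularity, mean intensity, intensity s.d.) over the pre-division
window — an exhaustive search over contiguous splits minimizing within-class
variance, earliest split on ties — and anchors MA as the first post-division
frame whose sister-centroid distance exceeds a threshold (default 10 px at
0.65 um/px, scaled physically; the division frame itself is the fallback).
Tracks whose best split barely beats a constant model
(`cost_constant / cost_best < 1.2`) are flagged low-confidence rather than
rejected. Any per-frame classifier can plug in through the probability-table
interface: `viterbi_decode()` post-processes per-frame state probabilities
with an HMM permitting only `1->2->3` (self-transition 0.9, advance 0.1,
start in 0 or 1, absorbing invalid state); a decoded all-0 path rejects the
track. `builtin_state_probs()` provides a fixed-coefficient softmax on
condensation evidence and sister distance as a trainable-classifier-free
default. Manual annotation replaces an interactive GUI with a CSV of two
frame indices per cell (last interphase frame, early anaphase frame, or a
reject flag); annotations are copied verbatim to the sibling daughter. With
1-based frames, `last_interphase = L` puts IP at `L + 1` and
`early_anaphase = E` puts MA at `E + 1`.

**Derived features and statistics.** Series can be smoothed (moving average,
lowess, Savitzky–Golay; edge windows truncate to the available samples — the
convention under which a window-3 moving average of `0,3,0,3,0` starts with
`mean(0,3) = 1.5`), normalized to the cell's own interphase mean or to the
first late-anaphase value, and summarized by windowed OLS slopes (default
5-frame window) at an anchor. The interphase-recovery series is
`R(t) = 100 - mean_f min(100, |v_f(t) - mu_f| / mu_f * 100)` over the
feature set (area, minor axis, mean intensity, intensity s.d. by default):
100 means every selected feature sits exactly at its interphase mean, and
clipping per-feature deviations at 100% keeps `R` in [0, 100] even for
intensity overshoots (clipping can be disabled). Reporting the *complement*
of the mean deviation is a deliberate reading of "100% indicates full
recovery". Group comparisons use the standard tests (two-sample t,
one-way ANOVA, Wilcoxon, Kruskal–Wallis) plus a two-way treatment-by-time
ANOVA on series resampled onto the aligned axis (IP-to-MA block stretched
onto 10 bins by default — how variable-length blocks enter the two-way
layout is otherwise unspecified, and uniform resampling is the simplest
monotone, anchor-preserving choice). Fold-change ranking compares the
interphase average with the average of the first two state-2 and first two
state-3 frames per feature, ranks by the larger absolute log2 fold, and
emits a static single-directory HTML report with PNG figures. Multiple
feature tests report Benjamini–Hochberg adjusted p-values next to the raw
ones.

## What the synthetic generator emulates — and what it does not

`generate_movie()` renders the phenomena the pipeline measures, with
complete ground truth (centroids, label masks, states, anchors, lineage):

* interphase ellipses (radius 9 px ≈ 12 um diameter at 0.65 um/px) doing
  small random walks (0.5 px/frame — cultured epithelial-like cells move
  little);
* chromatin condensation at IP: area shrinks by `0.6^2` and the mask mean
  intensity rises by 1.8x (applied exactly, background included), in one
  frame — at 3-minute sampling, condensation onset is effectively a
  single-frame step;
* an elongated metaphase plate (axis ratio ~0.5) whose orientation
  oscillates ±15 degrees with a 12-frame period, exercising the angular
  features;
* sisters separating 11 px apart at the division frame along a random axis,
  at 2 px/frame/pole for 10 frames, then creeping at 0.1 px/frame so the
  distance stays strictly monotone while plateauing as real sister distances
  do;
* telophase decondensation relaxing daughters linearly back to ~0.92x
  interphase geometry over 15 frames;
* a spindle-like second channel between the poles during mitosis, fading
  after anaphase;
* smooth super-Gaussian (`exp(-rho^6)`) radial profiles rather than binary
  disks, so Otsu and the watershed are non-trivially exercised, plus
  Gaussian read noise (s.d. 8 on an amplitude of 120 over background 10).

The default parameter set *is* the package's reference study: 20 cells, 5
divisions (frames 40–56), 120 frames of 560x560 px. Cells are placed on a
jittered grid (pitch = spacing + 10 px) resembling a semi-confluent culture;
configurations whose masks would overlap are rejected as invalid rather than
rendered.

Passing tests on this generator shows the pipeline recovers *known*
geometry, kinetics and anchors under realistic noise — it does not show
robustness to phenomena the generator omits: uneven illumination and drift,
apoptosis and fusion, crowded/touching nuclei (handled only via external
instance labels), cell types with strong migration, out-of-focus frames, or
photobleaching. Real-data performance must be judged with the annotation
file format and the evaluation helpers.

## Numerical choices

* Frames and pixels are 1-based `(row, col)`; windows are closed R-style
  index ranges. One convention, used everywhere.
* Intensities are kept on the unsigned 16-bit scale; 8-bit input upcasts
  without rescaling.
* Otsu uses 256 uniform bins over the patch min–max range; the returned
  threshold is the chosen bin's upper edge, ties to the lowest boundary.
* TC3 and Viterbi ties resolve to the earliest split / lowest state index.
* The watershed floods in a compiled priority queue with insertion-order
  tie-breaks; results are bit-reproducible.
* Degenerate inputs propagate as flagged `NA`s (empty masks, constant
  patches, zero interphase means, eroded-away regions), never as silent
  zeros.
* Projects persist via native serialization with an embedded schema tag and
  version; fusion disambiguates clashing cell ids with a position prefix.
  CSV export prints 17 significant digits so re-import is bit-exact.

## Problem sizes used by the test suite

The unit suite exercises a 6-cell/2-division/110-frame movie (360x360 px)
end to end and the acceptance suite additionally runs the full 20-cell
reference study; oracle checks use 100–500 randomized cases per operation
(exhaustive Viterbi enumeration up to `4^8` sequences, literal double-loop
Haralick and TC3 evaluators, 200-patch Otsu scans). These sizes were chosen
as the smallest that exercise every code path with comfortable margins.

## Known limitations

* Gap closing across missed detections is not implemented; a lost frame
  terminates the track (and excludes the pair if inside the window).
* Divisions with more than two same-cluster successors are rejected, not
  resolved.
* The two-seed watershed cannot split cells that touch the central cell;
  supply instance labels for crowded fields.
* The LSTM-based validity/state classifiers of interactive workflows are
  represented only by the probability-table interface; the built-in
  per-frame model is intentionally simple.
* Channel alignment is assumed, not verified.
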