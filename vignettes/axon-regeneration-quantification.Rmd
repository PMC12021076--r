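---
title: "Quantifying axon regeneration and retinal cell survival: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying axon regeneration and retinal cell survival: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonreg)
```

## The quantification scheme

After an optic nerve crush, regenerating retinal ganglion cell (RGC) axons
are anterogradely labeled (CTB conjugated to a fluorophore), the cleared
nerve is imaged as a confocal stack with 2-µm z spacing, and regeneration is
scored by a small set of conventions that this package implements as code:

* **Optical sections.** Every 4 consecutive slices are max-projected into an
  8-µm optical section (`project_z()`, `group = 4`); merging all slices
  gives the full maximum-intensity projection (`project_stack()`).
* **Fiber counts.** In each optical section, fibers are counted where they
  cross lines perpendicular to the nerve axis at 250-µm intervals distal to
  the crush site, until the first distance at which no signal is visible;
  counts at each distance are summed over all sections (`count_fibers()`).
  A "fiber" on a counting line is a maximal suprathreshold pixel run of at
  least 2 pixels; runs separated by a background pixel are distinct. The
  sum-over-sections rule is reproduced literally, which means an axon
  spanning two optical sections is counted in both — the stated procedure
  is replicated rather than "corrected", and the behaviour is pinned by a
  two-section fixture in the test suite.
* **Lengths.** The regeneration length of an axon is the arc length of its
  longest root-to-tip path, from the terminal back to the crush site; the
  summary is the mean of the top 5 longest axons (`axon_lengths()`).
* **Tip morphology.** The maximal width of the axonal tip, as a ratio to
  the adjacent shaft diameter, classifies the terminal: ratio strictly
  greater than 4 is a retraction bulb, anything else (including exactly 4)
  a growth cone (`measure_tip()`, `classify_tip()`).
* **Trajectories.** The direction of the tip over a terminal window is
  compared with the nerve's longitudinal axis; an angle above 90° is a
  U-turn. The U-turn rate divides flagged axons by analyzed axons (top 20
  longest in the nerve, or all axons entering the chiasm), at most one
  U-turn per axon. The branching index divides terminal tip count by
  analyzed axon count (`detect_uturn()`, `trajectory_metrics()`).
* **Chiasm fates.** Axons reaching the chiasm are classified by the region
  containing their terminal: pre-chiasmic (stopped or turned back before
  the optic nerve–chiasm transition zone), ipsilateral or contralateral
  optic tract, or contralateral optic nerve (`classify_chiasm_fates()`).
* **Retina.** RGC survival is the ratio of Tuj1+ cell counts in injured
  versus uninjured whole-mount retina fields (percent); transduction and
  marker fractions are double-positive over Tuj1+ counts
  (`survival_rate()`, `marker_fraction()`); intensity comparisons are
  background-subtracted per-cell means relative to the control condition
  (`relative_intensity()`).
* **Sciatic nerve.** Peripheral-nerve regeneration lengths are measured
  from the crush site to the distal tip, and nerves with fewer than 15
  identifiable axons fail QC and are excluded (`sciatic_regeneration()`).
* **Statistics.** Two-tailed Student's t (pooled variance) for two
  unnormalized groups, one-sample t against the reference for
  control-normalized data, and one-way ANOVA with Tukey HSD for three or
  more groups; significance at p < 0.05 (`two_sample_t()`,
  `one_sample_t()`, `anova_tukey()`).

The original measurements of this kind are made manually (ImageJ). The
package automates each step and — because no imaging data of this kind can
be regenerated at a desk — validates every step against a synthetic-data
generator with known ground truth.

## What the generator simulates

`simulate_nerve()` draws a population of regenerating axons from the crush
plane (coordinate convention: physical µm, crush plane at x = 0, growth
toward +x):

* **Extension lengths** follow a truncated exponential with mean
  `length_scale`. This is a stand-in law chosen for its qualitative match
  to the decay of fiber counts with distance; it is pluggable and must not
  be read as a biological claim.
* **Trajectories** are correlated random walks with per-step angular noise
  (`tortuosity_sd`), mean reversion toward the axis, and a hard clip of the
  heading at 70° from the axis. The clip guarantees that an axon not
  assigned a U-turn can never read above the 90° threshold, so generated
  labels are always consistent with realized geometry.
* **U-turns** (probability `p_uturn` per axon) are one terminal reversal:
  a short straightening run, a smooth in-plane arc of radius `turn_radius`
  through past 160°, and a reversed tail of ≥ 40 µm, so any direction
  window near the end reads above 90°.
* **Branches** arrive as a Poisson process along arc length
  (`branch_rate` per mm), with lengths capped at `branch_max_len` and
  always shorter than the remaining main path, so the main tip keeps the
  morphology and U-turn labels.
* **Tips** are bulbs with probability `p_bulb`; ground-truth tip/shaft
  ratios are drawn from `bulb_ratio_range` (entirely above 4) or
  `gc_ratio_range` (entirely below 4), so labels never straddle the
  classification threshold.
* **Lanes.** Start points sit on a jittered grid with `lane_spacing`, and
  each walk is reflected back into a lateral corridor
  (`corridor_radius`). With sufficient spacing, axons are guaranteed not
  to touch — the regime in which exact oracle equivalence (crossing
  counts, tip counts, per-axon labels) is meaningful. Dense, overlapping
  nerves are exactly the regime the flags of `trace_axons()` report rather
  than resolve.
* **Randomness.** One root seed; per-axon substreams are derived by
  counter, so adding axons never perturbs earlier ones, and identical
  configurations are bit-reproducible.

The exact crossing count of every polyline with every 250-µm plane is
computed from the geometry and stored, which gives `count_fibers()` an
exact oracle.

`simulate_chiasm()` lays trajectories through landmark regions (OCTZ plane,
tract-entry plane, midline plane) according to configured fate
probabilities; contra-lateral fates cross the midline inside the chiasm by
construction. `simulate_retina_pair()` draws Tuj1+ cells at a Poisson
density (scaled by `survival_fraction` in the injured arm) with
non-overlapping placement, Bernoulli Cre/p-S6 co-expression, and renders
Gaussian-spot channel images with additive noise.

## The imaging model

`rasterize_stack()` renders axons as tubes of the shaft diameter with the
terminal widened to the true tip ratio, converts local chord thickness to
expected photons (`photon_scale` per µm), applies an anisotropic Gaussian
PSF (lateral `psf_sigma`, axial `psf_sigma_z`, default 3× lateral — the
usual confocal elongation), and draws Poisson shot noise on signal plus
background, plus optional Gaussian read noise. Two numerical choices
matter:

* **Axial partial-volume integration.** With 2-µm sections and ~1-µm tube
  radii, sampling at voxel centres would let a tube vanish wherever it
  runs between two slice planes. An optical section integrates light over
  its thickness, so the rasterizer measures the axial distance from the
  voxel's z-slab rather than its centre. Without this the rendered tube
  fragments — an artifact of sampling, not of imaging.
* **Noise-free contract.** With `psf_sigma = 0` and `shot_noise = FALSE`
  the suprathreshold mask equals the exact tube rasterization, which the
  tests exploit for geometry oracles.

## Tracing

No 3D skeletonizer exists among the installed toolchain, so
`trace_axons()` implements the standard geodesic tracer design: foreground
voxels form a 26-connected graph whose edge costs are physical step lengths
down-weighted by the Euclidean distance transform (so geodesics run along
tube centrelines); each component touching the crush plane (within
`root_tol`, default 20 µm) is converted to a rooted tree by iterative
farthest-point extraction with coverage marking; terminal spurs shorter
than `prune_len` (default 10 µm) are pruned; trees shorter than
`min_length` are dropped with a count. The root is taken on the
crush-plane-most voxel layer (else the segment between root and plane
would appear as a spurious branch). Centrelines are smoothed with a short
moving average to suppress voxel-chain zigzag before lengths are measured.

Two caveats are inherent to the approach and flagged rather than hidden:
merged bundles (axons whose tubes touch) are traced as one tree and
reported via the `multi_contact` flag — disentanglement is out of scope —
and the traced main path ends at the end of the fluorescent structure,
which lies about one tip radius beyond the generating polyline's terminal.

Tip widths are measured as twice the distance transform along the
centreline. Morphometry is best performed on the merged Z-projection
(`project_stack()` then `binarize()`), matching how these measurements are
made in practice; in 3D the axial PSF inflates the apparent shaft width
and compresses the tip/shaft ratio toward the threshold.

## Parameter defaults and problem sizes

All defaults are exposed and logged through `run_config()`: counting
interval 250 µm, slice group 4, ratio threshold 4, U-turn angle 90°,
top-5/top-20 selections, 15-axon QC minimum, direction window 20 µm, tip
window 10 µm, shaft window 20 µm starting 10 µm proximal to the tip
window. Where the procedure leaves a choice open, the package picks one
and exposes it: per-axon U-turn accounting (the alternative event-count is
`count_reversal_events()`); distances measured along the axis (crushed
nerves are imaged straightened); the counting-line run rule (≥ 2 pixels).

Pixel sizes in the validation suite are chosen so structures are resolved:
0.5 µm default (a 2-µm shaft spans 4 pixels; the ≥ 2-pixel run rule then
counts single axons as single fibers), 0.25 µm for tip morphometry
(quantization below 5% on a 1-µm shaft radius), 0.7 µm for the bulk
pipeline recovery runs. Validation problem sizes — 20 nerves of 25 axons
for the crossing oracle, 200 axons × 50 seeds per U-turn probability for
label agreement, 100-120 single-axon stacks per probability level through the full image
pipeline, 50 seeds of paired 6-field retinas, 10,000 null replicates for
the type-I error — were fixed as desk-scale study conditions before the
checks were run.

## What passing tests do and do not show

The generator produces sparse, lane-separated, singly-labeled axons with
unambiguous ground truth; real cleared-nerve stacks contain crossing and
fasciculating axons, uneven labeling, vignetting and tile seams (inputs
here are assumed pre-stitched), none of which are simulated. Oracle
equivalence therefore validates the *bookkeeping* — that the code computes
the stated quantities exactly when the scene is unambiguous — and
parameter recovery validates robustness to PSF blur and shot noise at
moderate levels. Neither certifies performance on densely fasciculated
tissue, where the merged-bundle flag, not the tracer, is the honest
output.

## Known limitations

* The tracer does not disentangle crossing axons; merged components are
  flagged, not split.
* The truncated-exponential length law and all rate parameters are
  simulation conveniences, not biological estimates.
* The tip/shaft ratio measured through heavy blur is biased low (halo adds
  to the shaft faster than to the bulb); measuring on the 2D projection
  mitigates but does not remove this.
* `count_fibers()` requires the nerve axis along the image x axis; rotate
  stacks (or supply trees directly, image-free) otherwise.
* The literal sum-over-projections rule double counts axons spanning
  section boundaries; output metadata carries the stop distance and
  threshold so the choice is auditable.
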