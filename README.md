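# axonreg

Automated quantification of axon regeneration after nerve injury, with a
ground-truth simulator that makes every metric testable.

Studies of optic-nerve regeneration score their imaging data with a small
set of manual conventions: confocal stacks of the cleared nerve (2-µm z
spacing) are max-projected into 8-µm optical sections (4 slices each);
CTB-labeled fibers are counted where they cross lines at 250-µm intervals
distal to the crush site, summed over sections; the mean length of the top
5 longest axons is measured from the tips back to the crush site; axonal
tips are classified by the maximal tip width over the adjacent shaft
diameter (ratio > 4 = retraction bulb, otherwise growth cone); a trajectory
whose terminal direction exceeds 90° to the nerve axis is a U-turn, with
the rate taken over the top 20 longest axons (or all axons entering the
optic chiasm); the branching index is terminal tips over analyzed axons;
axons at the chiasm are classified as pre-chiasmic or as projecting into
the ipsilateral tract, contralateral tract, or contralateral nerve; RGC
survival is the Tuj1+ cell-count ratio of injured to control whole-mount
retinas, and AAV transduction the Cre/Tuj1 double-positive fraction;
sciatic nerves with fewer than 15 identifiable axons are excluded. Groups
are compared with two-tailed Student's t, one-sample t for
control-normalized data, or one-way ANOVA with Tukey HSD, at p < 0.05.

`axonreg` implements this scheme as tested code for anyone who needs the
measurements to be reproducible rather than manual: a synthetic-data module
generates nerves, chiasm trajectories and retina fields with known ground
truth; an imaging module rasterizes them into realistic fluorescence stacks
(anisotropic PSF, Poisson shot noise); a tracing module converts stacks
back into rooted axon trees (geodesic centreline tracing over the
26-connected foreground voxel graph); and metric modules compute every
quantity above, each validated by oracle equivalence or parameter recovery.

## Worked example

Simulate a nerve whose axons make U-turns half the time, image it, trace
it, and score it:

```r
library(axonreg)

cfg <- nerve_sim_config(n_axons = 3, p_uturn = 0, branch_rate = 0,
                        tortuosity_sd = 0, flat = TRUE, lane_spacing = 20,
                        nerve_radius = 100, nerve_length = 1000, seed = 2)
gt  <- simulate_nerve(cfg, lengths = c(300, 600, 900))
st  <- rasterize_stack(gt, imaging_config(psf_sigma = 0, shot_noise = FALSE,
                                          background = 0))
pz  <- project_z(st, group = dim(st$data)[3])
count_fibers(pz, gt$geometry, threshold = 5)
#>   distance_um count
#> 1         250     3
#> 2         500     2
#> 3         750     1
#> 4        1000     0
```

Three axons of 300/600/900 µm cross the 250-µm line three times, the
500-µm line twice and the 750-µm line once — the counts match the exact
plane-crossing table stored in `gt$crossing_table`. The same stack traces
back to three trees whose lengths match the generator:

```r
tr <- trace_axons(binarize(st, "fixed", threshold = 1), gt$geometry)
tr
#> <trace_result: 3 tree(s), 0 dropped below min length>
round(axon_lengths(tr$trees, k = 5)$per_axon_lengths, 1)
#> [1] 606.2 301.8 902.8   # ground truth plus the ~1-3 um terminal structure
```

(the traced main path runs to the end of the fluorescent structure, about
one tip radius past the generating polyline's terminal; trees are returned
in voxel-component order, not length order).

Trajectory metrics and tip morphology follow the same pattern
(`trajectory_metrics()`, `measure_tip()`, `detect_uturn()`), retina
quantities come from `simulate_retina_pair()` → `quantify_retina()`
(survival, transduction, marker fractions), and `two_sample_t()` /
`one_sample_t()` / `anova_tukey()` compare the resulting tables.

The `analysis/` directory holds a worked study over two simulated cohorts
(poorly vs strongly regenerating): `01_simulate_cohorts.R` through
`06_statistics.R` write their tables under `results/`. The methods
vignette (`vignettes/axon-regeneration-quantification.Rmd`) documents the
model, parameter defaults and validation design.

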