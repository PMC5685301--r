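---
title: "Quantifying NMJ colocalization and stimulus-avoidance behaviour in larval zebrafish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying NMJ colocalization and stimulus-avoidance behaviour in larval zebrafish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfcipn)
```

## The measurement problem

Chemotherapy-induced peripheral neuropathy (CIPN) models in larval
zebrafish are read out in two complementary ways. First, structurally:
confocal stacks of trunk muscle are double-stained for a presynaptic
vesicle marker (SYT2, red) and the postsynaptic acetylcholine receptor
(fluorescent alpha-bungarotoxin, green), and the degree to which the two
signals colocalize is taken as a proxy for intact neuromuscular junctions.
Second, functionally: groups of ~50 free-swimming larvae in agarose
troughs are shown a moving-bar visual stimulus under one half of the
trough, and healthy larvae move away from it, while larvae with impaired
motor function do not.

`zfcipn` implements both quantification arms plus the group statistics
that connect them, and pairs each arm with a ground-truthed simulator so
that every estimator can be validated by parameter recovery.

## Imaging arm

The per-larva procedure mirrors the standard ImageJ/Fiji workflow for
this assay family:

1. **Maximum-intensity Z projection** (`max_z_projection()`) over a
   selected window of optical slices — typically 10 slices of roughly
   1 µm each, covering the lateral muscle just beneath the epidermis.
2. **Kapur maximum-entropy threshold** (`kapur_threshold()`) per channel:
   the threshold `t` maximizes the sum of Shannon entropies of the
   normalized histogram restricted to background (bins ≤ t) and
   foreground (bins > t). Candidates that leave either partition empty
   are skipped; ties break toward the smallest `t`, so results are
   reproducible. 8-bit images are thresholded on their native levels;
   deeper images are min–max binned to 256 levels and the bin threshold
   is mapped back to the native scale (`histogram_256()`,
   `native_threshold()`).
3. **Masking** (`apply_threshold_mask()`): intensities strictly above
   threshold are kept, the rest zeroed — the mask-and-image-calculator
   step of the original workflow.
4. **ROI cropping** (`crop_roi()`), e.g. to exclude the myoseptum.
   Cropped pixels are removed from the *analysis domain*, not set to
   zero: percent-positive metrics and correlation coefficients use the
   cropped denominator, so cropping cannot bias them by injecting
   artificial zeros.
5. **Colocalization**: `manders_coefficients()` computes
   M1 = Σ red over green-positive pixels / Σ red and the converse M2 on
   the already-masked channels (the analogue of running Coloc2 with
   auto-thresholding off), and `pearson_coefficient()` the product-moment
   correlation over in-domain pixel pairs. A channel left empty by
   masking makes its coefficient undefined; it is returned as `NA` with a
   warning and excluded from group means — never silently reported as 0.
6. **Particle analysis** (`analyze_particles()`): 8-connected components
   of the binary mask (the ImageJ default connectivity), per-particle
   pixel and calibrated µm² areas, and the percent of in-domain pixels
   above threshold. Because it works on the binary mask it is insensitive
   to staining intensity. No particle size filter is applied by default.

`quantify_nmj()` chains the steps and returns one tidy `nmj_metrics`
row per larva; `measure_axon_length()` converts traced polylines (e.g.
CaP motor axons) to calibrated lengths.

```{r imaging-example, eval = FALSE}
sim <- generate_nmj_stack(synthetic_nmj_params(coloc_fraction = 0.5),
                          seed = 42)
quantify_nmj(sim$stack, larva_id = "demo")
```

### Numerical choices

* Indices are R-idiomatic: 1-based, inclusive slice windows and ROI
  bounds.
* The Kapur tie-break (smallest maximizing `t`, with a 1e-12 floating
  point tolerance treated as a tie) makes thresholds deterministic.
* For deeper-than-8-bit data the 256-level binning uses bin width
  `(max − min + 1)/256` on the observed range; the native threshold is
  the largest intensity in the selected bin, so the native mask rule
  `intensity > threshold` selects exactly the foreground bins.
* Degenerate inputs fail loudly: single-valued histograms (no threshold
  separates anything), empty analysis domains after cropping, and
  all-zero channels are errors or `NA`-with-warning, never silent zeros.
* `quantify_nmj()` accepts fixed manual thresholds
  (`thresholds = c(red = , green = )`) in place of the automatic Kapur
  step. This matters for noiseless validation constructions: on a
  zero-background noise-free image the maximum-entropy criterion
  legitimately places the threshold high inside the blob-intensity range
  (its two-partition entropy sum keeps rising as the bright tail is
  split), so exact-recovery checks use an explicit zero threshold while
  all realistic-SNR analyses use the automatic path.

## Behaviour arm

`trajectory_set()` binds per-larva tracks (id, frame, time, x, y in mm)
to the trough geometry and stimulus protocol. Two metrics are computed:

* **Percent down** (`percent_down()`): for every frame in the stimulus
  window, the fraction of tracked larvae in the half of the trough away
  from the moving bar; the metric is 100 × the mean over frames. Larvae
  exactly on the midline are counted as *stimulated*-half occupants, a
  deliberate bias against detecting avoidance. The pre-stimulus baseline
  is summarized separately (`window = "baseline"`) and never mixed into
  the stimulus metric. Healthy avoidance pushes the value above 50.
* **Swim speed** (`swim_speed()`): per larva, the summed Euclidean
  displacement over consecutive frames divided by elapsed time, over the
  whole recording by default (the assay does not restrict speed to the
  stimulus period). Lost-tracking frames break displacement pairs rather
  than interpolating; larvae missing more than half their frames are
  dropped with a warning.

`summarize_groups()` reports group means with standard errors
(sample SD/√n).

## Group statistics

Imaging metrics in this assay family are compared after **modified
Thompson tau** outlier rejection (`thompson_tau_outliers()`): with `n`
current values, `τ = t·(n−1)/(√n·√(n−2+t²))` where `t` is the two-sided
Student quantile at α/2 on n−2 df; the single point with the largest
absolute deviation is removed if it exceeds `τ·s`, and the rule is
iterated. Rejection is applied independently within each treatment
group, before means and tests, which is why per-group n's can differ.

`t_test_groups()` is the pooled-variance Student two-sample t-test
("t-test" in this literature conventionally means the pooled Student
form; the choice is recorded in the result's `method` field). One-tailed
tests require the caller to state the direction — appropriate when the
hypothesis only admits a deviation on one side, as with stimulus
avoidance that can only be reduced by impairment. Zero-variance samples
are handled as limits (equal means: p = 1; unequal: p = 0, with a
warning). `compare_groups()` packages rejection + summaries + pairwise
tests.

## The simulators and what they do (not) emulate

### NMJ stacks

`generate_nmj_stack()` emulates the acquisition regime of the assay:
10 optical slices at 1 µm, 128×128 px at 0.2 µm/px, 8-bit. Green
AChR-like clusters (Gaussian radius 1 µm) are placed uniformly;
`round(coloc_fraction × n_red_puncta)` red SYT2-like puncta (radius
0.3 µm) are centred inside randomly chosen clusters with jitter up to
half the cluster radius, the rest placed away from clusters. PSF blur is
applied analytically — a Gaussian object convolved with a Gaussian PSF is
exactly a Gaussian with variances summed — with a 3× larger axial sigma,
typical of confocal optics. Poisson shot noise acts on the object signal,
then a constant background (8) and Gaussian read noise (SD 2) are added
and intensities quantized. Peak intensities (140/160) were set so the
default Kapur threshold separates signal from background at this SNR.

The simulator does **not** render myotomes, myosepta, anisotropic axon
geometry, chromatic offsets, or depth-dependent attenuation. Passing the
recovery suite therefore shows the estimators are correct and monotone
under controlled punctate imagery — not that biological segmentation
difficulties (dense neuropil, bleed-through) are solved.

### Plate-assay tracks

`generate_behavior()` produces a reflected persistent random walk for
each of 50 larvae in a 50×10 mm trough: 900 s white-background baseline,
then a 600 s moving-bar stimulus under one half, at 1 frame/s. Each
frame, a larva currently *over the bar* reorients toward the safe half
with probability `p_avoid`; larvae already in the safe half swim
undisturbed, so occupancy equilibrates instead of absorbing at 100%.
Walls reflect both position and heading. Positions are reported at 1 µm
resolution (typical of centroid tracking), which also makes CSV round
trips exact.

Free parameters were fixed once against the generator's own design
requirements: cruise speed 1.5 mm/s and heading noise 0.3 rad/frame give
realistic bout-like persistence, keep the displacement shortening
intrinsic to wall reflections well under the 10% speed-recovery band,
and mix occupancy fast enough that the null (p_avoid = 0) percent-down
statistic concentrates near 50 (measured SD ≈ 1.3 across seeds at the
default geometry). Treatment effects (e.g. vincristine) are modelled
only as user-supplied parameter shifts — lower `p_avoid`, lower speed,
lower `coloc_fraction` — never as hard-coded biology.

## Orchestration

`run_all()` ties the arms together for a configured set of groups:
simulate → quantify (both arms) → Thompson-tau + t-test comparisons →
CSV outputs plus a JSON manifest recording the config, the master seed,
derived stage seeds and MD5 hashes of every output, so any number in a
report can be traced to its inputs. `read_run_config()` accepts YAML or
JSON. A thin command-line wrapper with subcommands (`simulate-nmj`,
`simulate-behavior`, `quantify-nmj`, `quantify-behavior`, `compare`,
`run-all`) ships in `inst/cli/zfcipn.R`.

## Validation scale

The test suite validates each primitive against an independent oracle
(exhaustive entropy search for Kapur; a union-find/graph labelling for
particles; the textbook formulas for Pearson, tau and the pooled t) and
the full pipelines by parameter recovery: a 5-point `coloc_fraction`
grid × 20 seeds for M1 (Spearman ρ ≈ 0.98), the same design for
`p_avoid` → percent-down, 10,000 null simulations for t-test
calibration, and 20-seed null bands for occupancy. These sizes keep the
whole suite under a minute on one core while leaving the recovery
statistics far from their pass boundaries.

## Known limitations

* Colocalization is 2D, computed on projections as in the source
  workflow; volumetric (3D) colocalization is out of scope.
* No image registration or deconvolution; channels are assumed aligned.
* The myoseptum ROI is user-supplied, not auto-detected.
* No multiple-testing correction is applied across metrics, matching
  the assay convention of reporting per-metric t-tests.
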