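---
title: "Orbital neural geometry from mixed sensorimotor selectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orbital neural geometry from mixed sensorimotor selectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurorbit)
```

## The scientific problem

During flexible manual interception, a primate reaches to where a moving
target *will* be, not where it is. Motor cortex activity around movement
onset (MO) therefore carries both the upcoming reach direction and the
sensory context (target angular velocity) that shaped it. `neurorbit`
implements the full analysis chain for asking how target motion modulates
reach-direction coding:

1. single-neuron statistics — directional tuning indices and a statistical
   classification of target-motion modulation into preferred-direction (PD)
   shift, gain, and offset (additive) effects, plus nonlinear tuning-model
   fits compared by adjusted R²;
2. population geometry — single-trial neural states by PCA, per-condition 3D
   ellipse fits, and tilt / rotation / shift metrics of the "orbital"
   arrangement those states form;
3. population decoding — sliding-window and cross-condition transfer
   decoding with linear multiclass SVMs;
4. a task-trained recurrent network whose node population reproduces the
   same geometry, with ablation, connection-scaling, connectivity and
   latent-dynamics comparison analyses;
5. a synthetic-data generator that produces model-neuron populations and
   noisy recorded-style sessions with known ground truth, so every stage of
   the chain can be validated end to end.

The task geometry is fixed throughout: targets move on a circle of radius
15 cm (0.15 a.u. in the network world) at -240, -120, 0, 120 or 240 deg/s
(counterclockwise positive), reach endpoints are grouped into eight
45-degree sectors anchored at 0 degrees (half-open bins; the anchor is a
convention and affects no downstream metric), and the delay between target
onset and the GO cue is uniform in 400–800 ms.

## Representational model neurons

Three model-neuron families combine a Gaussian temporal profile (sd 30
bins, peak near bin 100 = MO), cosine tuning in reach direction theta, and a
sigmoidal modulation by the abstract velocity code vel = 1..5 (3 = static):

* gain: `exp(-(t-tmu)^2/1800) * (sig(g*(vel-3)) * cos(theta-pd) + 1)`,
  `g ~ U[0,1]`;
* PD shift: `exp(...) * (cos(theta - pd - 90*sig(s*(vel-3))) + 1)`,
  `s ~ U[0,1.5]`;
* additive: `exp(...) * (cos(theta-pd) + sig(g*(vel-3)) + 1)`.

The standard simulation crosses 5 velocities with 64 directions (320
trials, 200 time bins) and draws `tmu ~ N(100, 10)`. Preferred directions
sit on a deterministic uniform grid rather than being drawn at random: the
grid is one realization of "uniformly distributed" and removes a variance
source from the explained-variance summaries. Rates are averaged over bins
50–150 (the MO window), z-scored per neuron and decomposed by PCA; with 300
pure-gain neurons the first two components carry ~98% of the variance and
the per-condition rings tilt monotonically with velocity, while the pure
additive group yields parallel rings displaced along PC3 with zero tilt.
We z-score before PCA for model data exactly as for recorded-style data,
keeping a single preprocessing path; the additive group's PC3 share is the
one quantity visibly sensitive to this choice.

## The synthetic recorded session

`generate_noisy_session()` maps the same tuning equations onto real units:
velocities in deg/s enter the sigmoid through the symmetric code vel/120
(so the slope parameter stays O(1)), parameters are in spikes/s with
baselines keeping rates positive, and trial noise interpolates towards
Poisson spike counts in the 200 ms analysis window. `noise = 0` produces a
fully deterministic session — rates equal the tuning means and endpoint
angles sit at the exact sector centers — which is the regime in which the
modulation classifier must recover every generated label exactly. With
`noise > 0`, endpoints are jittered uniformly within their sector and
Poisson count noise is scaled in, giving an SNR controlled jointly by
`noise` and `rate_scale` (Poisson noise grows as the square root of the
rate). What the generator does *not* emulate: spike-train timing structure,
slow drifts and waveform-sorting artifacts, correlated (shared) noise
across neurons, and non-cosine tuning shapes. Passing recovery tests
therefore show the statistics are correct and well calibrated under
independent Poisson-like noise, not that they are robust to every failure
mode of real recordings.

## Classification of target-motion modulation

Per condition, three indices are computed from the MO ± 100 ms window: the
PD (vector sum of the eight sector-mean rates at the sector centers), the
tuning depth (max - min of sector means) and the offset (mean rate). The
statistical criteria (all at p < 0.05, each moving condition against the
static one, no multiple-comparison correction) are:

* **PD shift** — Watson–Williams test on PD samples. The samples are
  independent PD estimates from disjoint stratified splits of each
  condition's trials (default 5 splits, each split contributing one PD from
  its own sector means). This construction keeps the named test while tying
  its power to the data: the standard error of a split-mean difference
  equals the standard error of the full-data PD estimate, whereas a
  bootstrap-sample version would make power an arbitrary function of the
  resample count. Zero-dispersion groups are resolved exactly (p = 1 when
  the group means agree, p = 0 otherwise), which is what makes noiseless
  recovery exact.
* **gain** — two-tailed Wilcoxon signed-rank on the eight paired per-sector
  tuning depths |sector mean − condition mean|. A pure gain change scales
  all eight deviations the same way (all signs agree; p = 0.0078 is
  attainable at n = 8); a pure PD rotation permutes them with mixed signs
  and cannot reach significance, and a pure offset change leaves them
  untouched.
* **addition** — the same signed-rank on the eight paired sector means. A
  pure offset change moves all eight in the same direction; a pure gain
  change moves near-PD and anti-PD sectors in opposite directions and
  cancels exactly on the symmetric sector grid.

A unit with no flag and no direction tuning (Kruskal–Wallis across sectors)
is labelled *none*. Flags may co-occur, representing mixed selectivity.

## Tuning-model fits

Five nonlinear models are fitted to single-trial rates by
Levenberg–Marquardt least squares, multi-started over eight initial PDs
(ties broken by residual, then by the smallest sigmoid slope |a2|), with
`vc = vel/120`:

| model | form | parameters |
|---|---|---|
| simple | `a1*cos(th-pd) + c1` | 3 |
| gain | `(a1*sig(a2*vc) + c2)*cos(th-pd) + c1` | 5 |
| additive | `a1*cos(th-pd) + a3*sig(a2*vc) + c1` | 5 |
| PD shift | `a1*cos(th - pd - a5*sig(a2*vc)) + c1` | 5 |
| full | additive + gain + shifted-cosine terms, shared slope | 8 |

The PD-shift form follows the shifted-cosine term of the full model (the
natural one-mechanism reduction); the full model keeps the sigmoid slope
`a2` distinct from the additive coefficient (`a3o`). Goodness of fit is the
standard adjusted R², `1 - (1-r2)(n-1)/(n-p-1)`. Fits are reported in a
canonical form with nonnegative cosine amplitude so that PDs are
identifiable modulo 360 rather than 180. Family comparisons across a
population use one-tailed Wilcoxon rank-sum tests on the adjusted-R²
vectors.

## Neural states and ellipse geometry

States are single-trial projections: average the rates in a 100 ms window,
z-score per neuron (dropping zero-variance units), project onto the first
three PCs. Each velocity condition's point cloud is fitted with a 3D
ellipse: the plane by total least squares (the normal is the direction of
least variance), then the numerically stable direct least-squares conic fit
of Halir & Flusser constrained to an ellipse in-plane. The fit quality
`r2 = 1 - sum(d^2)/sum(|p - centroid|^2)` uses the true 3D point-to-ellipse
distance (in-plane nearest point by Newton refinement, plus the
out-of-plane component). Degenerate clouds (collinear points, hyperbolic
conics) raise errors rather than returning nonsense.

Metrics against the static-condition ellipse:

* **tilting angle** — the angle between plane normals folded into
  (-90, 90]. The sign convention follows the task's circular geometry:
  the common tilt axis is the leading principal direction of the moving
  conditions' normal components orthogonal to the static normal, oriented
  so counterclockwise target motion takes positive sign; each condition's
  sign is its normal component along that axis. The empirical content is
  the linearity and magnitude of tilt versus velocity and the sign
  *consistency* within rotation directions — the CCW-positive orientation
  itself is the convention.
* **rotation angle** — circular mean over sectors of the PC1–PC2 angular
  difference between matched sector centroids (about each condition's own
  centroid center). This metric lives in the projection plane, so unlike
  tilt and shift it is only approximately invariant under 3D rotations of
  the cloud.
* **state shift** — RMS 3D distance between the two ellipses sampled at 64
  matched normalized arc-length parameters, with the starting phase
  anchored at each condition's sector-1 centroid and the traversal
  direction fixed by sector 2. Because this metric also responds to ring
  *size* changes (the signature of gain modulation), the summary
  additionally reports `shift_vertical`, the ellipse-center displacement
  along the static normal, which isolates the layering characteristic of
  additive modulation: the pure-gain group has `shift_vertical = 0` while
  the pure-additive group's grows with |velocity|.

`align_static_plane()` applies the proper rotation taking the static normal
to the z-axis (reflections excluded), used for display and for testing that
the metrics are rotation-invariant.

## Decoding

Rates are soft-normalized (`rate / (range + 5)`) and decoded with linear
multiclass SVMs (libsvm's one-vs-one reduction, default regularization):
8-way reach direction (chance 1/8) and 5-way target velocity (chance 1/5),
in 100 ms windows sliding by 50 ms under repeated 10-fold cross-validation.
Transfer decoding trains on one condition set and tests on another
(CCW vs CW, |120| vs |240|, static vs moving for the direction decoder;
sector splits for the velocity decoder), repeating the random train/test
draw to obtain accuracy distributions compared by paired one-tailed
t-tests. Soft-normalized (not z-scored) inputs are used for both temporal
and transfer decoding, keeping one preprocessing path. For network nodes,
decoding runs on the leading PCs of the window activity to mute inactive
units.

## The interception network

200 rectified-tanh rate units, time constant 50 ms, Euler-integrated at
dt = 10 ms (well below tau/2; halving dt changes validation endpoints by
less than the trial-to-trial sd). Inputs: intention (the interception
point, present only from MO-50 ms to MO), target position (throughout), and
a GO step. Output: 2D hand velocity following a minimum-jerk speed profile
towards the interception point. Trial timing: delay U[400, 800] ms,
reaction time U[150, 250] ms, movement time U[250, 400] ms — variable
timing matches the behaving-animal regime and keeps the post-MO analysis
window inside every movement.

Training minimizes the mean squared output error plus the activity penalty
`alpha * sum_t sum_n r^2` (alpha = 1e-7) with Adam at learning rate 0.001,
batches of 32 trials from a 640-trial pool, and gradient-norm clipping at
1. The batched BPTT/Adam loop runs in compiled single-precision code (the
float noise floor is orders of magnitude below the trial-to-trial loss
variance); all analyses use a double-precision forward pass. Two
initialization choices deserve note:

* The recurrent matrix is `N(0, g/sqrt(N))` with g = 1.5 by default; a
  `j_init_scale = "N"` switch provides the `g/N` alternative. The sqrt-N
  scaling is the standard choice that keeps recurrent input variance
  O(1) at initialization.
* The input matrix B is `N(0, 1/sqrt(n_inputs))`, not zero. With B, W and
  the initial state all zero, the rectified-tanh network sits at an exact
  fixed point with identically zero gradient for every parameter — no
  first-order method can leave it. Random input weights break that
  degeneracy; the readout W starts at zero, so the untrained network
  outputs exactly zero.

Training runs of 1,200–3,000 steps reach mean validation endpoint errors of
0.004–0.012 a.u. against a target radius of 0.15 (the figure of merit
is error below radius/10). The node population then reproduces the orbital
geometry: per-condition ellipse R² in the 0.86–0.99 range and tilt linear
in signed velocity with slopes of 0.23–0.29 degrees per deg/s — the same
regime as the behaving-animal fits (0.15–0.26) though steeper than the
0.15 reported for the published network ensemble. Prolonged training
steepens the tilt further until the fastest conditions approach degenerate
near-vertical planes (and, for some seeds, an |velocity|-tilt solution in
which both rotation directions tilt the same way), so the standard runs
stop at 1,200 steps, where the endpoint error has plateaued and the
geometry is stable across analysis draws.

A related reproducibility note: the node-modulation composition of these
independently trained networks is PD-shift rich (>90% of active nodes) and
addition poor (<10%), whereas the published ensemble reports roughly
balanced gain/shift/addition fractions. The pervasive PD shifts are a real
feature of our solutions, not a test artifact: the apparent PD of
target-input-driven nodes rotates with the velocity-dependent lead angle
between the target's peri-movement position and the reach endpoint (median
PD range across velocities is ~50 degrees), and any calibrated test flags
them. The composition is sensitive to training details that published
descriptions do not pin down (initialization of the input weights, training
duration, trial-timing distribution); we verified that the qualitative
orbital geometry survives all of the variants we explored.

Perturbations zero all connections touching a node subset (`ablate`) or
scale class-to-class recurrent blocks (`scale_connection`); both leave the
original model untouched. `connectivity_summary` reports mean |J| per class
pair (self-weights excluded) with a Kruskal–Wallis omnibus.
`compare_latent` reduces two bins-by-features matrices to 30 PCs and
reports the first ten canonical correlations and the symmetric Procrustes
disparity.

## Numerical choices and degenerate inputs

* Angles are degrees everywhere, CCW positive; circular means via the
  resultant vector; the Watson–Williams F uses the standard von Mises
  concentration correction and an exact branch for dispersion-free groups.
* Signed-rank tests with all-zero differences return p = 1 (no evidence of
  change) instead of erroring.
* Uniform-rate direction tuning yields an undefined PD, flagged rather than
  silently zero.
* PCA drops zero-variance neurons with a message; requesting more PCs than
  trials errors.
* The ellipse fit refuses clouds with fewer than 8 points, fewer than 5
  sectors, collinear geometry, or a hyperbolic best conic.
* All stochastic stages take explicit integer seeds; identical seeds give
  bit-identical results (single-threaded BLAS assumed for the network
  training path).

## Problem sizes used by the test-suite and acceptance runs

The shipped tests run the full chain at desk scale, chosen to exercise
every code path with comfortable statistical margins: model populations at
the standard 300/320-trial size (explained-variance summaries averaged
over 20 seeds); synthetic sessions of 18–24 neurons at 8–20 trials per
condition cell; three networks trained for 1,200 optimizer steps and
validated on 200–500 fixed trials, with classification and geometry on 8
trials per condition cell. The ensemble summaries in the published-scale
protocol (100 models, 1,000 transfer repetitions) are exposed through the
same functions via their `n_models`, `reps` and `seeds` arguments.

## Known limitations

* The recorded-data ingestion path expects rate tensors; there is no
  spike-sorting or event-extraction front end.
* The modulation classifier's reconstruction of the depth/offset tests
  (eight paired per-sector statistics) is one defensible reading of a
  procedure that is underdetermined from published descriptions; its
  cross-talk properties (gain cannot masquerade as addition and vice versa
  on the symmetric sector grid) are verified in the tests.
* Network modulation-type fractions depend on the trial-timing
  distribution and training length; the qualitative composition (gain and
  PD-shift rich, addition present, few unclassified nodes) is stable, the
  percentages move by tens of points across reasonable settings.
* dPCA, ICA, continuous-output decoding and trajectory-distance analyses
  are out of scope.
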