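---
title: "Recognizing individuals from locomotion: the riemgait model and its design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing individuals from locomotion: the riemgait model and its design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the representation

Two people walking at the same speed still move differently: joint
amplitudes, phase relations between hip and knee, and harmonic content of
the swing are individual-specific. `riemgait` identifies individuals from 3D
skeletal locomotion by measuring exactly those differences.

A skeleton is a rooted kinematic tree of `J` joints. Each of the `B = J - 1`
bones contributes only its *direction* — the unit vector from parent to
child joint — so a pose is a point on the product manifold
`S² × S² × … × S²` (one 2-sphere per bone). This deliberately destroys bone
lengths: raw joint positions encode each person's static skeleton, which
would make recognition trivial and meaningless (a subject could be
identified while standing still). The direction convention is parent→child;
the opposite choice relabels every sphere point consistently and does not
change any distance the pipeline computes.

All intrinsic geometry on the sphere is carried by three maps:

* `sphere_log(b, p)` — the tangent vector at `b` pointing along the
  geodesic to `p`, with norm equal to the arc angle;
* `sphere_exp(b, v)` — its inverse, walking arc length `||v||` from `b`;
* `geodesic_distance(x, m) = acos(<x, m>)`, with the inner product clamped
  to `[-1, 1]` for floating-point safety near coincident vectors.

The log map is undefined at the antipode; the package raises a classed
error there rather than returning an arbitrary branch.

## Preprocessing: cycles, periods, alignment

Locomotion is periodic, and the recognition unit is one gait cycle.

**Period detection.** The speed of a reference joint (an ankle: the foot
meets the ground first, so its speed carries the clearest cycle structure)
is the per-frame displacement norm times the frame rate. Its raw
autocorrelation `R(lag) = mean(v_i * v_{i+lag})` peaks at multiples of the
stride period. Two practical hazards shape the detector:

1. *Harmonic sub-periods.* A rectified speed signal (`|velocity|`) has
   several bumps per stride, so `R` also peaks near `T/2` or `T/3`. Those
   peaks are systematically lower than the peaks at multiples of `T`, but
   not by a dramatic margin in the raw profile, because the squared-mean
   offset inflates everything. The detector therefore subtracts the profile
   median and scores every candidate peak lag `q` by the mean adjusted
   height near *all* its multiples `q, 2q, 3q, …`: the true period scores
   highest since all its multiples are strong, while a harmonic candidate
   is dragged down by its weak intermediate peaks. Among near-ties (within
   10%) the smallest lag wins, so `2T` never beats `T`.
2. *Long-lag variance.* The unbiased `1/(n - lag)` normalization makes
   long-lag estimates noisy and often slightly too large; peak heights are
   therefore tapered by `(n - lag)/n` (the biased-estimator weighting)
   before scoring.

Inside `extract_cycles` the speed series is additionally smoothed with a
5-frame moving average before the profile is computed. Per-frame measurement
jitter differentiates into substantial white speed noise; the smoothing
suppresses it and changes nothing on clean signals. `speed_autocorrelation`
itself is left exact so its values match hand computation.

**Cut points.** The period detector gives `T` but not where to cut. Cycles
are cut at successive minima of the (smoothed) reference-joint speed —
minima approximate ground contact — searched in windows `[0.8T, 1.2T]`
ahead of the previous cut, preferring genuine local minima nearest the
expected spacing so that flat stance phases do not let the cut drift.
Trailing partial cycles are dropped; cycles outside ±20% of the detected
period are discarded.

**Alignment.** Different cycles have different lengths and local tempo.
Each cycle is aligned to a reference — the medoid under summed per-frame,
per-bone geodesic distance after uniform manifold resampling — by dynamic
time warping whose frame-to-frame cost is the sum of bone geodesic
distances. Warping duplicates frames; duplicated runs are replaced by
geodesic interpolation between the nearest distinct frames (motion should
never freeze), and the result is uniformly resampled on the manifold to a
common `target_frames` (default 150; the synthetic experiments use 40 to
match their 40-frame strides). This is a deliberate, fully specified
substitute for generalized time warping, which the original formulation
delegates to an external method.

## Features

**Mean motion sequence.** For each frame and bone, the Karcher mean of the
aligned cycles' directions is computed by iterated tangent-space averaging:
`m ← exp_m(step * mean(log_m(x_s)))` until the mean tangent norm falls
below `grad_tol` (default 1e-6; step 1, the classical iteration, which
contracts whenever the points lie in an open hemisphere — comfortably true
for aligned gait data, where same-frame bone directions cluster tightly).
The defaults are a numerical choice of this package; the loop-termination
condition is "iterate until the mean tangent is small", the only reading
under which the iteration minimizes the sum of squared geodesic distances.

**Geodesic features.** A cycle's spatial feature matrix is
`G[f, b] = geodesic_distance(x_f^b, m_f^b)` — how far this person's pose
sits from the population mean pose, per frame and bone, in radians. The
printed form of this feature in the source formulation is a matrix square
root of an outer product of the log vector with itself; the only scalar
reading is the Euclidean norm of the log, i.e. the geodesic distance, which
is what is implemented. `G` flattens row-major by frame into `G(s)` of
length `F·B`.

**Temporal hierarchy of covariance.** `G`'s rows over a frame window are
summarized by their sample covariance (denominator `n − 1`; windows are
half-open `[f1, f2)`, under which the printed `1/(f2 − f1 − 1)` *is* the
textbook unbiased estimator — an inclusive reading would give `n − 2`,
which matches no covariance estimator). The default `"figure"` scheme uses
one top-level window over all `F` frames plus seven second-level windows of
length `⌊F/4⌋` whose starts are evenly spaced to cover the sequence
(~50% overlap), eight matrices total. The `"paper_dim"` scheme drops the
top level, giving descriptor length `7·B(B+1)/2`, the printed dimension of
the source formulation; figure and printed dimension disagree (8 vs 7
blocks), so both readings are available, figure-faithful by default. The
exact second-level lengths/offsets are not specified anywhere; the evenly
spaced `⌊F/4⌋` windows are one consistent realization, fixed and
documented. Flattening takes each window's upper triangle (with diagonal)
row-major, in window order.

## Kernels and metric learning

Spatial vectors `G(s)` and temporal descriptors `C(s)` are each mapped
through an RBF kernel whose bandwidth is the mean pairwise training
distance, and fused by the Hadamard (entrywise) product — positive
semidefinite by the Schur product theorem. Column `n` of the fused matrix
is sample `n`'s feature vector; a query's vector is its cross-kernel
column against the training samples with training bandwidths (required for
honest cross-validation; never stated in the source, but the only
leakage-free reading).

The classifier is k-NN under a learned Mahalanobis-type metric
`D(i, j) = ||L(k_i − k_j)||²` with `L ∈ R^{p×N}` low-rank. The loss pulls
each sample toward its `n_targets` same-class neighbours, hinges impostors
(`zeta` margin) at least as far away as any target pair, and penalizes
`λ‖LᵀL − I‖_F`:

* The published gradient for this loss omits the `μ/(1−μ)` weights and the
  hinge indicator, and its regularizer term corresponds to a *squared*
  Frobenius penalty while the loss prints an unsquared one. The optimizer
  must descend the stated loss, so the implemented gradient differentiates
  the loss exactly (unsquared penalty, `λ·2L(LᵀL−I)/‖LᵀL−I‖_F`, zero
  subgradient at zero) and is validated against central finite differences
  in the test suite.
* `L` is initialized from linear discriminant analysis: the top `C − 1`
  generalized eigenvectors of the between/within scatter (within-scatter
  ridge-regularized), padded to `p` rows with principal components
  orthonormalized against them. `p` defaults to `N`, matching the
  reference experiments where the learned dimension equals the training
  size.
* Training is gradient descent with a backtracking line search (start
  1e-3, halve on increase, accept on decrease) — the learning rate is
  unstated in the source, and the line search guarantees the monotone loss
  history the tests assert. Stopping: 40 epochs or gradient Frobenius norm
  below 0.01 (the stated settings), or a stalled line search.
* Impostor candidates are simply all differently-labelled samples each
  epoch; the hinge's active set selects violators exactly, equivalent to
  an active-set refresh at these training sizes (N ≈ 112) with no
  approximation.
* `ζ = 1` (the classical large-margin convention), `n_targets = 3`,
  `k_classify = 3`; all unstated in the source and exposed in the config.
  `μ = 0.2`, `λ = 0.1` are the stated defaults.

**Evaluation.** Stratified 5-fold cross-validation repeated (default 10
times; the scaled experiments use 2–3 repeats and say so). Bandwidths and
`L` are always estimated on training folds only. Whether the mean motion
sequence itself should be computed per training fold is ambiguous in the
source; computing it on all data leaks test information into every feature,
so `evaluate_cycles()` recomputes it from training folds by default and
offers `leaky_mean = TRUE` for the all-data variant. Accuracies are
reported per fold, per repeat, and as the grand mean (both aggregation
orders are available in the result).

## The synthetic world

No mocap download is assumed; the generator produces the data the pipeline
claims to handle, with known ground truth.

Each subject's style perturbs a shared gait template: per-joint sinusoidal
angles `mean + amp·sin(2πt/T + phase) + h_amp·sin(4πt/T + h_phase)` driven
through a rigid forward-kinematic chain (19-joint full body by default,
with 9- and 6-joint reductions for fast tests), a forward-translating root
with a small double-frequency vertical bob, alternating legs, counter-
swinging arms, and a skewed hip second harmonic (forward swing faster than
the return, as in real gait — this asymmetry is also what gives the ankle
speed a clear fundamental period, a property the pipeline's period detector
relies on). Between-subject spread scales log-normal amplitude multipliers,
phase shifts, posture offsets, and a ±10% stride-period factor; bone-length
dispersion is a separate knob so that "same dynamics, different skeleton
size" worlds can be generated. Within-subject variation is a random trial
phase plus white per-frame angle jitter (default 0.02 rad).

Defaults are fixed once: 7 subjects × 20 sequences (one retained cycle
each, the scale of a small mocap identification study), 40-frame strides at
40 fps, spread 1 ≫ noise 0.02. Four strides are simulated per sequence —
enough for the autocorrelation profile to contain at least two true-period
multiples, which the comb-score detector needs.

What the generator does *not* emulate: ground-contact physics, soft-tissue
and marker noise, out-of-sagittal-plane rotation variety, camera pose
estimation error, or distorted trailing poses. A green end-to-end test
therefore establishes that the pipeline recovers subject-specific
*dynamics* planted in periodic kinematic chains — not field performance on
optical mocap.

Two identifiability dials are tested: with spread ≫ noise, fused-feature
CV accuracy is ≥ 0.95; with identical dynamics and only bone lengths
varying, accuracy sits at chance — the representation provably discards
static skeleton size. On the default dataset the fused kernel is at least
as accurate as either single mode; across other generator seeds fusion can
occasionally trail the best single mode by a small margin when the temporal
descriptor is much weaker than the spatial one.

## Numerical choices and degenerate inputs

* Inner products are clamped to `[-1, 1]` before `acos`.
* Antipodal log maps, degenerate (zero-length) bones, non-orthogonal
  tangents, empty point sets, too-short sequences, and flat (aperiodic)
  speed profiles raise classed errors (`riemgait_error_*`) naming the
  offending frame/bone/file where applicable.
* Karcher iterations report per-entry final gradient norms and iteration
  counts in the mean sequence's `convergence` field.
* k-NN vote ties break by smallest summed distance, then label sort order —
  fully deterministic.
* All generator and evaluation randomness flows from explicit seeds;
  repeated runs are bit-identical, and library code restores the caller's
  RNG state.

## Known limitations

* DTW-to-medoid alignment is pairwise, not a joint multi-sequence
  optimization; cycles whose cut phase differs grossly from the medoid's
  would align poorly (cut-point placement at speed minima keeps phases
  consistent in practice).
* The covariance descriptor treats matrices as flattened vectors, not as
  points on the SPD manifold (by design, matching the source formulation).
* The BVH reader supports the common position/rotation channel subset only
  and errors on anything else rather than guessing.
* Training cost is dominated by per-fold mean-sequence recomputation in
  honest evaluation mode; `leaky_mean = TRUE` trades honesty for speed.
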