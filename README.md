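# riemgait

Individual recognition from 3D skeletal locomotion, for biometrics and
motion-analysis researchers working with mocap-style joint trajectories.

Everyone walks differently — joint amplitudes, hip/knee phase relations,
harmonic content of the swing are subject-specific — but raw joint
positions also encode each person's static skeleton, which would make any
recognition experiment trivial. `riemgait` removes the skeleton and keeps
the dynamics: every bone contributes only its unit direction, so a pose is
a point on the product manifold **S² × S² × … × S²** (one 2-sphere per
bone) and all comparisons use intrinsic (geodesic) geometry.

The pipeline:

1. **Cycle segmentation** — the stride period is detected from the raw
   autocorrelation of the ankle speed,
   `R(Δf) = 1/(F−1−Δf) Σ v_i v_{i+Δf}`, and cycles are cut at successive
   speed minima (≈ ground contact).
2. **Manifold alignment** — cycles are warped to a common length by
   dynamic time warping with per-frame summed geodesic cost against a
   medoid reference; duplicated frames are repaired by geodesic
   interpolation.
3. **Mean motion sequence** — per frame `f` and bone `j`, the Karcher mean
   `m_f^j = argmin_m Σ_s d²(m, x_f^j(s))` over all aligned cycles, by
   iterated tangent-space averaging (log/exp maps on S²).
4. **Features** — spatial: the geodesic distance matrix
   `G[f, j] = d(x_f^j, m_f^j)`; temporal: a two-level hierarchy of
   covariance matrices of `G`'s rows over overlapping windows, upper
   triangles concatenated (`C(s)`).
5. **Kernel fusion + metric learning** — RBF kernels over `G(s)` and
   `C(s)` (bandwidth = mean pairwise training distance) fused by the
   Hadamard product; a low-rank transform `L` is learned by gradient
   descent on the large-margin loss
   `ε(L) = μ Σ [D(i,j) − D(l,i) + ζ]₊ + (1−μ) Σ D(i,j) + λ‖LᵀL − I‖_F`
   with `D(i,j) = ‖L(k_i − k_j)‖²`, LDA initialization, and k-NN
   classification under `D`.

A forward-kinematic synthetic gait generator (subject-specific oscillation
styles driven through a rigid chain) makes every stage testable without any
dataset download, including chance-level negative controls.

## Worked example

```r
library(riemgait)

cfg <- gait_sim_config(n_subjects = 4, cycles_per_subject = 8,
                       frames_per_cycle = 40, skeleton = "mid9", seed = 7)
ds <- generate_dataset(cfg)
ds$sequences[[1]]
#> <rg_joint_seq> 'subj01_t001' subject=subj01: 160 frames x 9 joints @ 40 fps

cs <- extract_cycles(to_pose_sequence(ds$sequences[[1]], ds$skeleton),
                     ds$sequences[[1]], "lankle")
cs
#> <rg_cycle_set> 3 cycles, detected period 36 frames
```

Subject 1's style drew a 36-frame stride (the nominal 40 ± a per-subject
factor); three complete cycles fit in the 160-frame trial, the trailing
partial cycle is dropped. One cycle per sequence is kept, aligned, and
summarized against the mean motion sequence:

```r
cycles <- lapply(ds$sequences, function(s)
  extract_cycles(to_pose_sequence(s, ds$skeleton), s, "lankle")$cycles[[1]])
aligned <- align_cycles(cycles, 40)
ms <- compute_mean_sequence(aligned)
ms
#> <rg_mean_seq> 40 frames x 8 bones; max final ||v|| = 3.08e-08

G <- geometric_features(aligned[[1]], ms)
summary(as.vector(G$G))   # radians from the mean pose, per frame and bone
#>      Min.   1st Qu.    Median      Mean   3rd Qu.      Max.
#> 0.0004338 0.0117013 0.0430518 0.0669013 0.0918890 0.3864416

temporal_hierarchy(G)
#> <rg_cov_descriptor> 8 windows, descriptor length 288
```

This cycle sits up to 0.39 rad from the mean pose — that deviation pattern
is the identity signal. Recognition by repeated stratified cross-validation
with fused kernels (mean sequences recomputed per training fold, so no test
information leaks into the features):

```r
res <- evaluate_cycles(aligned, ds$labels, mode = "fused",
                       n_folds = 4, n_repeats = 2, seed = 1)
sprintf("fused mean accuracy: %.3f", res$mean_accuracy)
#> [1] "fused mean accuracy: 0.953"
res$confusion
#>        subj01 subj02 subj03 subj04
#> subj01     16      0      0      0
#> subj02      0     16      0      0
#> subj03      0      0     14      2
#> subj04      1      0      0     15
```

95% of the 32 test classifications (×2 repeats) recover the right
individual; errors confuse the two subjects whose styles drew closest.

## Command line

```sh
inst/cli/riemgait simulate --out data/ --seed 1
inst/cli/riemgait features --in data/ --out feats/
inst/cli/riemgait evaluate --in feats/ --mode fused --report report.json
inst/cli/riemgait train    --in feats/ --model model.json
inst/cli/riemgait predict  --model model.json --in queryfeats/
```

Configuration is a YAML/JSON file (`--config`) over
`default_pipeline_config()`: metric weights `mu = 0.2`, `lambda = 0.1`,
margin `zeta = 1`, 40 epochs, gradient threshold 0.01, 150 target frames
per cycle, 5-fold × 10-repeat stratified CV. Unknown keys are rejected.

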