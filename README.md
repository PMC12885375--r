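# swmtools

Surface-based profiling of **superficial white matter (SWM)** — the
U-fiber-rich few millimetres of white matter directly beneath the cortical
gray/white matter (GM/WM) interface. The package is aimed at researchers
working with 3D histology or quantitative MRI (T1 maps, MTsat) who want to
characterize SWM microstructure *as a surface*, in register with the
overlying cortex, rather than as a voxel mask.

## What it does

1. **Equipotential surface placement.** Solve the Laplace equation
   ∇²u = 0 over the white-matter domain of a labeled segmentation, with
   u = 0 at the GM/WM interface and u = 1 at the ventricular walls
   (6-neighbor finite differences, SOR; sub-voxel Shortley–Weller boundary
   offsets). The GM/WM mesh is then advected along the unit field gradient,
   and a surface is emitted each time the *distance traveled* along the
   streamline crosses a multiple of the depth spacing — 50 × 0.06 mm for
   histology-resolution data, 15 × 0.2 mm for in-vivo 7T data, down to the
   3 mm maximum depth that spans the U-fiber system. The streamline
   correspondence is the identity over vertex index, so cortical labels and
   maps propagate losslessly into the SWM.
2. **Depth profiling.** Trilinear sampling of co-registered feature volumes
   onto every surface yields a depth × vertex intensity-profile matrix;
   per-depth statistical moments (mean, SD, Fisher–Pearson skewness, excess
   kurtosis), Tukey-fence outlier repair, iterative uniform-kernel surface
   smoothing (5 iterations, relaxation 0.5), and curvature regression are
   provided.
3. **Microstructural profile covariance (MPC) gradients.** Vertex profiles
   are rank-transformed, the cortex-wide average profile is partialled out,
   pairwise partial Spearman correlations are Fisher-z transformed
   (MPC = ½·ln((1+r)/(1−r))), the matrix is row-sparsified to its top 10%
   and turned into a normalized-angle affinity
   (1 − arccos(cos θ)/π), and diffusion map embedding (α = 0.5) yields the
   spatial gradients G1, G2, … with their eigenvalue spectrum.
4. **Spatially-aware statistics.** Connectivity strength (|Fisher z| row
   sums for functional, log streamline weight for structural connectomes),
   geodesic short-range masking (< 35 mm), Spearman map associations with
   gyral/sulcal splits, spin permutation tests (uniform random rotations of
   a spherical registration, nearest-vertex reassignment), and LOWESS group
   trends.
5. **Analytic phantoms.** A parallel-slab phantom (1D linear Laplace
   solution) and a concentric spherical-shell phantom
   (u(r) = (1/r − 1/b)/(1/a − 1/b)) with exact boundary level sets, planted
   depth-profile gradients, and synthetic connectomes give every stage a
   ground-truth oracle.

## Worked example

```r
library(swmtools)

## 1. a shell phantom: ventricle (r = 10 mm) | WM | GM/WM interface (r = 20 mm)
ph <- make_shell_phantom(voxel_size = 0.5)

## 2. Laplace field in the WM shell, then 15 surfaces 0.2 mm apart
field <- solve_laplace(ph$seg, tolerance = 1e-6)
stack <- shift_surface(ph$gm_wm_mesh, field, depth_spec("invivo"))

## 3. a depth-dependent feature volume with a planted regional gradient
V <- nrow(ph$gm_wm_mesh$vertices)
truth <- ph$gm_wm_mesh$vertices[, 3] / ph$params$b   # smooth pole-to-pole score
vol <- make_depth_intensity_volume(ph, profile_fn = function(d) 10 - d,
                                   planted_map = truth, noise_sd = 0.1, seed = 1)

## 4. profiles and per-depth moments
profiles <- sample_volume_to_stack(stack, vol, modality = "synthetic")
head(compute_moments(profiles), 4)

## 5. per-surface smoothing, MPC, diffusion-map gradients
adj <- mesh_geometry(ph$gm_wm_mesh)$adjacency
sm <- profiles
sm$values <- t(apply(profiles$values, 1, smooth_surface_map, mesh = adj))
gset <- mpc_gradients(compute_mpc(sm))

## 6. spin test against a synthetic connectome's nodal strength
fc <- make_synthetic_connectome(V, abs(truth) + 0.5, model = "fc", seed = 2)
spin <- spin_test(gset$gradients[, 1], fc_strength(fc), ph$gm_wm_mesh,
                  n_perm = 1000, seed = 3)
```

Output (what the code above actually prints):

```
<potential_field> 234544 WM voxels; residual 9.8e-07 after 185 iterations
<surface_stack> 16 surfaces, 642 vertices; depths [0, 3]; 100% valid
  depth  mean    sd skewness kurtosis
1   0.0 9.999 0.102    0.031   -0.433
2   0.2 9.800 0.232    0.012   -1.099
3   0.4 9.601 0.390   -0.008   -1.153
4   0.6 9.401 0.506   -0.011   -1.156
<gradient_set> 642 vertices x 10 gradients; G1 variance 51.4%
G1 vs |planted score| (Spearman): -0.687
<spin_result> rho = -0.687, p_spin = 0.000999 (1000 permutations)
```

Reading the numbers: the solver converges to the analytic shell solution
(max error 0.19% of the unit potential range); all 642 vertices reach every
depth, and the depth-0 row reads ~10.0 while each 0.2 mm step loses ~0.2
intensity units — exactly the generating profile 10 − d. The per-depth SD
grows with depth because the planted regional modulation is largest
mid-SWM. G1 explains 51% of the MPC variance and tracks the magnitude of
the planted modulation (see the methods vignette for why the leading axis
is magnitude- rather than sign-ordered in a near-noiseless phantom); the
spin test rejects independence from the planted connectome strength at the
permutation floor (p = 1/1001).

## Command line

```sh
inst/cli/swm phantom    --kind shell --voxel 0.5 --out ph/
inst/cli/swm sample-swm --seg ph/seg.nii.gz --surf ph/gmwm.surf.gii \
                        --preset histology --out stack/
inst/cli/swm profile    --stack stack/ --vol feature.nii.gz --out profiles.tsv
inst/cli/swm moments    --profiles profiles.tsv --out moments.tsv
inst/cli/swm gradients  --profiles profiles.tsv --sparsity 0.9 --alpha 0.5 --out gset/
inst/cli/swm associate  --gradient gset/G1.func.gii --feature curv.func.gii \
                        --sphere sphere.surf.gii --n-perm 1000 --seed 7 --out result.json
inst/cli/swm run-all    --config config.json --out run/
```

Exit codes: 0 ok, 1 user error, 2 internal error.

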