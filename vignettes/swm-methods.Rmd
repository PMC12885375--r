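---
title: "Surface-based superficial white matter profiling: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based superficial white matter profiling: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic phantoms do and do not establish, and the places where the
design was genuinely open and a choice had to be made. Every number quoted
here is computed by the test suite or by `scripts/acceptance.R`; nothing
is asserted that the code does not itself verify.

## 1. The equipotential model of SWM depth

Superficial white matter (SWM) is the thin, U-fiber-rich compartment
directly beneath the gray/white matter (GM/WM) interface. Its geometry
follows the cortical folds, so a fixed Euclidean offset from the interface
is a poor depth coordinate: opposing sulcal banks collide and gyral crowns
are oversampled. The package instead treats depth as progress along the
solution of a boundary-value problem. Let $\Omega$ be the white-matter
domain of a labeled segmentation. We solve the Laplace equation

$$\nabla^2 u = 0 \ \text{on}\ \Omega, \qquad
u = 0 \ \text{at the GM/WM interface}, \qquad
u = 1 \ \text{at the ventricular walls},$$

and advect every vertex of the GM/WM mesh along the unit field gradient
$\hat g = \nabla u / \lVert \nabla u \rVert$. Because $u$ is harmonic its
field lines never cross, so surfaces generated at increasing travel
distances nest without intersection — the property that makes the vertex
correspondence between cortex and SWM an identity over vertex index
(`propagate_labels()` is a reindex-free copy).

**Stopping rule.** A surface is emitted each time the *accumulated arc
length* of the streamline — the distance traveled — crosses a multiple of
the depth spacing. The alternative reading (stopping on iso-potential
values) would parameterize depth non-metrically; arc length equals true
metric depth on both phantoms and is what "0.06 mm spacing" plainly means.
Streamlines follow the *normalized* gradient, so the integration step is a
step in millimetres regardless of the local field magnitude.

**Presets.** `depth_spec("histology")` = 50 surfaces × 0.06 mm;
`depth_spec("invivo")` = 15 surfaces × 0.2 mm. Both reach 3 mm, deep
enough to span the U-fiber system and the superficial termination zones of
long-range bundles while staying above the centrum semiovale.

### Numerical scheme

The solver discretizes $\nabla^2 u$ with the 6-neighbor stencil
(anisotropic voxel spacing folded into the per-axis weights) and relaxes
with SOR ($\omega = 1.9$, fixed lexicographic sweeps, hence bitwise
deterministic) until the maximum absolute update falls below `tolerance`
(default $10^{-6}$).

The one place where we deviated from the obvious scheme is the boundary.
Fixing whole boundary-adjacent voxels to their Dirichlet values puts the
effective boundary at voxel centers, and on a curved boundary the
staircase error is $O(h)$: on the 0.5 mm shell phantom it reaches 5–9% of
the potential range, which would drown the quantities the surfaces are
meant to measure. We therefore use Shortley–Weller boundary arms: for a WM
voxel whose neighbor lies across a boundary, the Dirichlet value is
imposed at the estimated sub-voxel crossing point $\theta h$
($\theta \in (0,1]$), with the standard uneven-arm stencil weights
$2/(\theta(\theta+\theta_{\rm opp}))$. The crossing comes from a signed
level function evaluated at the two voxel centers:

* phantoms attach their *analytic* level sets (`lev_low`, `lev_high`) to
  the segmentation, so boundary placement is exact and the measured solver
  error is pure discretization error — 1.7 × 10⁻⁶ on the slab and 0.19% of
  range on the 0.5 mm shell (acceptance criterion 1);
* for binary-label-only input the level is a box-3 anti-aliased label
  indicator minus ½; boundary localization is then accurate to ~0.1–0.2
  voxel and the shell error rises to ~1.7% (max) / 0.14% (mean), the
  irreducible staircase limit of a label image — asserted as a regression
  bound in the unit tests;
* `subvoxel = FALSE` reproduces the plain half-voxel face convention.

Boundary faces touching neither Dirichlet region are zero-flux (Neumann),
which also handles WM islands and the lateral walls of the slab. Voxels in
$[0,1]$ are enforced by clamping (harmless at convergence: the exact
solution satisfies the maximum principle).

**Streamline integration** is explicit first-order with step
0.25 × min voxel size, the vector field trilinearly interpolated with
NaN-weight renormalization near the domain boundary. Seed vertices landing
marginally outside the sampled field (a staircase corner effect at the
interface) are sampled from the nearest in-domain voxel center within one
voxel — the vertex itself does not move, and arc length starts at the
seed. Halving the step changes final positions by less than the coarser
step (first-order convergence, tested), and the deepest histology surface
on the shell lands at 2.9993 mm against the 3 mm target (criterion 2).

### Equivolumetric intracortical surfaces

For the cortex above the interface the package provides the standard
equivolumetric construction: with outer/inner vertex areas $A_o, A_i$, the
surface bounding volume fraction $\alpha$ (counted from the white side)
sits at segment fraction
$\rho(\alpha) = \left(-A_i + \sqrt{\alpha A_o^2 + (1-\alpha) A_i^2}\right)/(A_o - A_i)$,
with the equidistant limit $\rho = \alpha$ when $A_o = A_i$. On concentric
10/11 mm spheres the mid-volume surface lands at the analytic
$\left((10^3+11^3)/2\right)^{1/3}$ radius to 4 significant digits. Within
the SWM itself placement is equipotential, not equivolumetric — there is
no second bounding surface below the interface — and the outermost
(CSF/GM) row of any intracortical profile is dropped before analysis to
limit partial-volume effects (`drop_outermost_row()`).

## 2. Profiling: sampling, moments, repair, smoothing

Feature volumes are sampled at surface vertices by mapping world
coordinates through the inverse affine and interpolating trilinearly —
exact for functions affine in voxel coordinates (machine precision,
criterion 3). Per-depth moments use the sample SD ($n-1$), Fisher–Pearson
skewness $g_1 = m_3/m_2^{3/2}$ and *excess* kurtosis $g_2 = m_4/m_2^2 - 3$
with biased central moments $m_k$; the conventions are stated because the
source material never fixes them, and the excess-vs-raw choice is a
constant offset that cannot change any depth-wise shape claim. Statistics
over fewer than 4 valid vertices are NaN, propagated rather than imputed.

Tukey repair flags values outside $[Q_1 - 1.5\,\mathrm{IQR},\ Q_3 +
1.5\,\mathrm{IQR}]$ using type-7 (linearly interpolated) quartiles — the
convention matters on small regions and is therefore pinned — and
replaces flagged vertices by the mean of their valid 1-ring, iterated to
closure, with the region median as the last resort. Non-flagged vertices
are never altered.

Surface smoothing is the uniform-kernel relaxation
$v \leftarrow (1-\lambda) v + \lambda\,\overline{v}_{\rm 1-ring}$ with
$\lambda = 0.5$, 5 iterations — the pre-MPC noise-control step. On a
degree-regular closed mesh it preserves the mean exactly; on an icosphere
(12 pentagonal vertices) the degree-weighted mean is the exact invariant
and the plain mean moves by $<0.5\%$ of the map SD. Curvature regression
(per depth, OLS of intensity on curvature; output = residuals + fitted
intercept) is exposed as an optional pre-MPC step; whether the original
pipeline applied it before or after MPC construction is unstated, and the
package leaves the order to the caller.

Mean curvature itself uses the umbrella estimator
$H_i = 2\,( v_i - \overline{v}_{\rm 1-ring})\cdot \hat n_i / \overline{\lVert v_j - v_i \rVert^2}$,
which is exact for symmetric vertex rings (unit sphere: $1 \pm 0.4\%$).
Its pointwise bias at irregular-valence vertices does not vanish with
subdivision (the *mean* absolute error does: 0.0020 → 0.0007 across two
subdivision levels), which is acceptable because every downstream use is
rank-based and any monotone-equivalent estimator gives the same Spearman
statistics. Sign convention: positive where the surface bulges along the
outward normal; on a GM/WM surface wound with normals out of the white
matter this makes sulcal fundi positive.

Geodesic distances are graph shortest paths along mesh edges with
Euclidean weights. The lattice metric overestimates true surface
geodesics by up to ~6% in off-axis directions on an icosphere — an
inherent property of edge-graph distances, not a convergence issue — which
is irrelevant at the coarse 35 mm threshold used for short-range masking
but stated here so nobody mistakes the function for an exact polyhedral
geodesic.

## 3. MPC and diffusion-map gradients

The microstructural profile covariance matrix is built as: rank-transform
each vertex profile over depths; form the cortex-wide average profile *in
rank space* (mean of the rank-transformed profiles); residualize every
rank profile on it (QR least squares); correlate residuals pairwise
(Pearson on rank residuals = partial Spearman); Fisher-z transform with
$|r|$ clipped to $1-10^{-7}$; zero the diagonal.

Two genuinely open choices were resolved as follows:

* **"log-transformation"** is implemented as Fisher z,
  $\tfrac12\ln\frac{1+r}{1-r}$. Any other monotone log-variant differs by
  a monotone rescaling and leaves every rank-based downstream statistic
  unchanged.
* **The controlled "average intensity profile"** is the *rank-space* mean,
  not the raw mean. The raw-mean variant demonstrably breaks the intended
  Spearman property that the matrix is invariant to a monotone transform
  of any single vertex profile (transforming one vertex changes the raw
  mean and hence everyone else's partial correlations); the rank-space
  mean preserves it exactly, and the property is tested.

A vertex whose profile is constant — or whose ranks coincide with the
average profile, leaving a zero residual — has undefined partial
correlations and is flagged; its row/column is NaN. `mpc_gradients()`
drops flagged vertices before embedding and returns NA gradients at their
positions. This degeneracy has measure zero in continuous data but occurs
in low-noise synthetic worlds with monotone depth baselines, so it is
handled rather than wished away.

The affinity kernel keeps, per row, the top
$\lceil (1-\text{sparsity}) V \rceil$ entries (default sparsity 0.9 →
top 10%, ties to the lower column index) and measures
$1 - \arccos(\cos(x_i, x_j))/\pi$ between sparsified rows. Negative
cosines are allowed (affinity below ½) to keep the kernel a true
normalized angle. The row-wise sparsification is asymmetric but the angle
re-symmetrizes; a final $(A + A^\top)/2$ guards against last-bit
asymmetry, which $\arccos$ amplifies unboundedly near $|\cos| = 1$.

Diffusion map embedding uses the anisotropic normalization
$W = D^{-\alpha} A D^{-\alpha}$ with $\alpha = 0.5$ (suppresses density
effects), the Markov operator $P$ = row-normalized $W$, and the
eigendecomposition of the symmetric conjugate
$D_2^{-1/2} W D_2^{-1/2}$ (numerically robust, provably the same
spectrum). The trivial stationary eigenvector (eigenvalue 1, constant
loadings) is dropped; gradient $k$ is $\psi_k\,\lambda_k/(1-\lambda_k)$
(diffusion-time-0 convention); signs follow the fixed rule "first nonzero
loading positive", making the pipeline deterministic end to end. The
implementation agrees with a plain dense eigensolver applied directly to
the nonsymmetric $P$ to $10^{-8}$ up to sign (criterion 6), and
`variance_explained()` reports eigenvalue shares over the retained
components.

## 4. Spin tests and connectivity context

Spatial maps on a cortical surface are smooth, so naive permutation nulls
are wildly anticonservative. The spin test rotates the spherical
registration coordinates by a uniform random rotation (QR of a Gaussian
matrix, determinant fixed to +1), reassigns one map by nearest original
vertex, and recomputes Spearman's rho; the two-sided p-value is
$(1 + \#\{|\rho_{\rm null}| \ge |\rho_{\rm obs}|\})/(1 + P)$, with floor
$1/(P+1)$. Two-sidedness is a package choice (the sidedness is unstated in
the source material). Nearest-vertex reassignment (not barycentric) keeps
the null map's value set identical to the original. Calibration is
verified by simulation: 200 independent smooth map pairs at 200
permutations give a rejection rate of 0.04–0.065 at nominal 0.05
(criterion 8). The registration argument may be a triangle mesh or a bare
V × 3 coordinate matrix (icospheres only exist at $V = 10\cdot4^k + 2$;
Fibonacci lattices cover arbitrary V).

Connectivity strength: functional strength is
$\sum_{j \ne i} |\mathrm{arctanh}(r_{ij})|$ (absolute Fisher z, direction
ignored); structural strength is $\ln(1 + \sum_j w_{ij})$ — the $+1$
guards isolated nodes and is monotone-equivalent to a plain log for every
rank-based analysis, which is why it is safe. Short-range masking zeroes
pairs at geodesic distance ≥ 35 mm (strictly-below retention matches the
"< 35 mm" rule). LOWESS trends use tricube-weighted local linear fits,
span 2/3 and one robustness iteration by default (no parameters are given
in the source material; these are the classical defaults).

## 5. The phantoms: what a green test establishes

The **slab** stacks CSF | GM | WM | ventricle along z. The GM/WM interface
and ventricular wall are voxel faces, the analytic potential is linear,
and true depth equals the z offset. The **shell** nests
ventricle (r ≤ a = 10 mm), WM (a < r ≤ b = 20 mm), GM (b < r ≤ c = 22 mm);
the potential is the spherical harmonic $(1/r - 1/b)/(1/a - 1/b)$ and
field lines are radial, so streamline length equals radial offset — the
placement oracle. Voxel presets: 0.5 mm (in-vivo-like) and 0.2 mm
(histology-like).

The intensity generator writes
`profile_fn(depth) + s_v · modulation(depth) + N(0, noise_sd)` per voxel,
with `s_v` looked up from the nearest seed vertex (grid index on the slab,
radial direction on the shell). The planted-profile generator
(`make_planted_gradient_profiles()`) writes the same model directly as a
depth × vertex matrix with iid noise and a centered, index-linear score.
Its default **modulation is one full sine period** over the depth range —
zero-mean over depth and hence nearly orthogonal to the controlled average
profile. This matters: a half-period (one-signed) modulation is mostly
absorbed by the mean-profile control, and at the stated noise (SD = half
the modulation amplitude) the planted gradient is then unrecoverable —
not a pipeline failure but a planted signal that the model is explicitly
built to remove. With the full-period default and the prescribed pre-MPC
smoothing, $|\rho_{\rm Spearman}(G_1, s)| \approx 0.93$ at V = 500,
D = 15 (criterion 7).

**What the phantoms do not emulate:** folded cortices (no sulcal banks, so
collision-free placement is not stress-tested), partial-volume and scanner
physics, spatially correlated noise (available as an option only), and
real histology artifacts beyond what Tukey repair models. A green suite
therefore establishes correctness of the numerics and the statistical
contracts — not robustness to every property of empirical data.

**A saturation effect worth knowing about.** Correlations are
scale-invariant, so as noise → 0 the partial correlation between two
planted profiles approaches ±1 regardless of how *strongly* each vertex
expresses the modulation; near the noiseless limit the MPC degenerates
toward a sign-block structure. In volume-sampled phantom runs (where
trilinear interpolation and surface smoothing leave very little
independent per-vertex noise) the leading embedding axis consequently
organizes vertices by the *magnitude* of their deviation from the mean
profile, with the sign-graded axis second. The demonstration pipeline
plants its connectome strength on the magnitude axis for this reason. At
realistic noise (the planted-profile world) the axes merge into a single
graded gradient and recovery is direct.

## 6. Determinism, formats, limitations

Every stochastic routine takes a `seed` and restores the caller's RNG
state; the solver, tracer and embedding are seed-free and bitwise
deterministic (fixed sweep order, fixed sign convention); a pipeline rerun
under the same config + seed reproduces numeric outputs byte for byte
(criterion 9). Volumes are NIfTI-1 (hand-rolled minimal codec — no NIfTI
reader exists in the supported dependency set — float64/int32 on write,
the common integer and float types on read, sform affine); surfaces and
per-vertex maps are ASCII GIFTI-style XML via xml2 (full double
precision, exact round trips); sidecars, manifests and configs are JSON.

Known limitations: no mesh decimation or template registration (external
tooling in the original workflows); no collision handling between adjacent
sulcal banks (irrelevant on the phantoms, real on folded anatomy); graph
(not exact) geodesics; the binary-label boundary estimator is ~0.1–0.2
voxel accurate, so label-only solves carry a few-percent worst-case
boundary error; hemisphere-mirrored spins for bilateral data are provided
as an option but not exercised by the tests.
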