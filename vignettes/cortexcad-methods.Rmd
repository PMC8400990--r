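---
title: "Regional cortical shape analysis for MCI diagnosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional cortical shape analysis for MCI diagnosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Mild cognitive impairment (MCI) is the intermediate stage between age-normal
cognition and dementia. Its anatomical signature on structural MRI is subtle:
group differences against normal controls (NC) are small and, crucially,
heterogeneous across patients — different people lose tissue in different
cortical regions. cortexcad implements a *regional* computer-aided diagnosis:
instead of a single whole-brain decision, every cortical region gets its own
calibrated probability of MCI-like shape change, and a second classifier
combines those 76 regional probabilities into the global NC/MCI call. The
per-region probability vector doubles as a personalized severity map that can
be painted onto the reconstructed cortical surface.

The pipeline assumes preprocessed inputs: skull-stripped T1 scans that have
been registered to MNI-152 space, together with their binary brain masks and
an integer AAL parcellation volume on the same grid. Registration, bias
correction and cortex segmentation are deliberately out of scope; background
voxels of a masked scan are exactly zero, an assumption several defaults
below rely on.

# Surface reconstruction

**Isovalue selection.** The reconstruction threshold is chosen from the
intensity histogram of the masked volume: build a 64-bin equal-width
histogram, drop the modal bin (the zero background of a masked scan), drop
bins holding under 1% of the remaining voxels, take the count-weighted median
of the surviving bins as the tissue bin, and return the midpoint between the
background-bin and tissue-bin centres. On a binary mask this yields exactly
0.5 and on a 0/100 two-level volume it yields 50, the two calibration cases
the rule is designed around. The bin count is a parameter; 64 bins put the
quantization error of the threshold near 1.5% of the intensity range.

**Isosurface extraction.** The surface is extracted by marching the lattice
cube by cube with each cube split into six tetrahedra sharing the cube's
main diagonal. Within a tetrahedron every marked/unmarked corner pattern has
a unique triangulation (one or two triangles on the crossed edges), with the
crossing placed by exact linear interpolation, so the vertex lies where the
interpolated intensity equals the isovalue. Because neighbouring cubes agree
on the shared face diagonal, the global surface is watertight by
construction; there is no saddle-face ambiguity case to resolve. This is the
reason the tetrahedral decomposition was chosen over the classic 15-case
cube table: the divergence-theorem volume below *requires* closed surfaces,
and the cube table needs an extra disambiguation rule to guarantee them.
The cost is a denser mesh (roughly twice the triangles for the same grid).
Triangle winding is oriented so normals point out of tissue; zero-area
triangles arising from crossings that coincide with lattice points are
removed. Each connected component is tracked separately.

**Volume.** The enclosed volume of a closed (component-wise) mesh is the
absolute sum of signed tetrahedron volumes `det(v1, v2, v3)/6` over faces —
exact for polyhedra, with no re-voxelization error. Per-region volumes mask
the intensity volume to the region's voxels, pad by one background voxel so
the surface closes at the grid boundary, and reconstruct that region
separately. On a 64³ ball phantom of radius 10 mm the mesh volume is within
0.5% of the analytic 4188.79 mm³; a partition of the ball into two labelled
halves reproduces the whole-ball volume within about 3% (the cut plane
crosses partial-volume voxels that neither half fully claims).

# Curvature descriptors

At every vertex the local surface patch is rotated into the tangent frame
(heights measured along the inward normal so that convex tissue has positive
curvature), and a quadric

$$f(x,y) = a x^2 + b y^2 + c x y + d x + e y + f$$

is fit by least squares to the vertices within a ring neighbourhood. The
principal curvatures are the eigenvalues of the Hessian form
`[[2a, c], [c, 2b]]`; when the fitted tangent plane is appreciably tilted
(fitted gradient norm `sqrt(d² + e²) > 0.05`, a rotation-invariant criterion)
the full first-fundamental-form correction `I⁻¹ II` is applied instead. From
the ordered pair λ₁ ≥ λ₂ the four descriptors are evaluated:

* Gaussian curvature λ₁λ₂ (1/mm²)
* mean curvature (λ₁ + λ₂)/2 (1/mm)
* sharpness (λ₁ − λ₂)² (1/mm²)
* curvedness √((λ₁² + λ₂²)/2) (1/mm)

**Neighbourhood size.** The ring radius is the estimator's main
bias–variance dial. Small patches track fine structure but make the
difference λ₁ − λ₂ (and hence sharpness) extremely noisy on discretized
surfaces; large patches smooth towards the osculating quadric. The default
is `rings = 5` (roughly a 5 mm patch at 1 mm voxels), calibrated on the ball
phantom: at radius 10 mm the median mean curvature is within 2% of 1/R,
median Gaussian curvature within 3% of 1/R², and median sharpness·R² ≈ 0.03,
while slab faces stay flat to ~0.0015/mm. At `rings = 2` the same fixture
shows an order of magnitude more sharpness noise, which is why the smaller
default was rejected. Degenerate fits (under 6 points or a rank-deficient
design) escalate the ring count up to `max_rings` before failing. For data
with structures much finer than ~5 mm, reduce `rings` and expect noisier
sharpness.

# Regional features

Mesh vertices are labelled by the atlas voxel containing them; because
surface vertices sit between tissue and background voxels, lookup uses a
one-voxel nearest-nonzero dilation of the atlas (most frequent neighbouring
label, ties to the smallest id) — without it roughly half the surface labels
as background. Per region the four descriptors are averaged over its
labelled vertices (median available via `statistic`), and the region's
enclosed mesh volume is appended, giving the fixed five-feature vector
(gaussian, mean, sharpness, curvedness, volume). Regions with fewer than 10
labelled vertices are flagged missing rather than zeroed; at classification
time missing cells are imputed with the training-set column mean.

Features are min–max normalized to [0, 1] per (region, feature) column. The
(min, max) pairs are estimated on training subjects only and re-applied
verbatim (with clipping) to held-out subjects — recomputing them on test
data would leak information into the fold. Constant columns are set to 0.5
with a warning, since they carry no discriminative information.

# Feature fusion by canonical correlation analysis

For two matched feature sets X (p×n) and Y (q×n), CCA finds transform
matrices Wx, Wy maximizing the correlation of the canonical variates under
unit-variance constraints; the solution solves the eigenproblem
`Sxx⁻¹ Sxy Syy⁻¹ Syx Wx = Δ² Wx`. The implementation uses the numerically
equivalent whitened form (SVD of `Sxx^{-1/2} Sxy Syy^{-1/2}`), which keeps
the variates exactly unit-variance and the canonical correlations sorted in
[0, 1]. The number of retained pairs d is the numerical rank of the whitened
cross-covariance (singular values above 1e-10 of the largest), floored at
one so a zero cross-covariance (possible after the constant-column rule)
still yields a zero-correlation variate instead of collapsing the chain.
Within-set covariances are ridge-regularized (`1e-8·trace/p`) only when
near-singular, so well-conditioned problems are solved exactly — on
one-dimensional inputs the canonical correlation equals |Pearson r| to
machine precision. The fused output concatenates both variate sets:
`Z = [Wx'(X − x̄); Wy'(Y − ȳ)]`, whose training covariance is the canonical
block matrix (identities on the diagonal, diag(δ) off it).

The five regional features are fused *sequentially*, two at a time in the
fixed canonical order: Z₁ = fuse(gaussian, mean), then Zₖ = fuse(Zₖ₋₁, next
feature). Scalar inputs give d = 1 at every step, so the fused
representation stays two-dimensional per region. The pairing order is
recorded in the fitted chain and configurable; with scalar features the
final subspace is largely order-insensitive, and a fixed order keeps models
auditable. Fitted chains are replayed on held-out subjects, never refit —
a deliberate strengthening over fitting the fusion transductively on the
whole cohort.

# Two-layer diagnosis

**Regional layer.** Per region, a support-vector machine (linear kernel by
default, C = 1) on the region's fused 2-vector, with probability
calibration by Platt scaling: an inner stratified 3-fold cross-validation
on the training portion produces out-of-fold decision values, to which the
sigmoid `P(MCI|f) = 1/(1 + exp(A f + B))` is fit by regularized maximum
likelihood with Platt's smoothed targets. Calibration is written in the
package rather than taken from the SVM library because the library's
built-in probability option uses unseeded internal randomization, which
would break reproducibility and the leakage audit; the hand-rolled version
is deterministic given the data and seed.

**Global layer.** A second SVM takes the vector of regional probabilities
and emits the NC/MCI call. MCI is the positive class throughout
(sensitivity = TP/(TP+FN)); a global decision value of exactly zero is
called MCI, favouring sensitivity at the knife edge. Regions missing in
more than half the training subjects are dropped with a warning.

**Evaluation.** Stratified k-fold cross-validation (k = 4 and 10 are the
reference settings) refits *everything* — normalization statistics, fusion
chains, both classifier layers — on each fold's training portion. Confusion
counts are pooled over folds; per-fold metrics are reported alongside. A
fold hash guarantees the comparison classifiers (decision tree, random
forest, k-NN on the concatenated fused features, plus the three SVM
kernels through the full two-layer pipeline) see identical splits. The
leakage audit refits a fold after deleting one held-out subject and checks
the md5 fingerprint of all training-derived state is unchanged.

Behavioural correlation analysis computes Pearson r with two-sided t-based
p-values between regional probabilities and any per-subject score columns,
with pairwise deletion; raw p-values are reported (as is conventional in
the source literature for such tables) together with Benjamini–Hochberg
q-values.

# Synthetic data

**Phantoms** stand in for preprocessed scans. Each shape (ball, ellipsoid,
axis-aligned cube, slab, two disjoint balls) carries its analytic volume and
surface curvature, so geometry tests never compare the pipeline against
itself. Occupancy is partial-volume antialiased by default — fractional
intensity in boundary voxels from the signed distance — because curvature
estimates on hard-binarized surfaces are markedly worse; both modes are
exercised in tests. Gaussian noise (default sd 2% of the tissue intensity)
is confined to tissue, matching the exact-zero background of masked scans.
Phantoms are bit-reproducible from their seed.

**Cohorts** stand in for the two-group study design (60 NC / 86 MCI at
baseline). Per subject and region, the five features share one latent
Gaussian factor: standardized value `loading·g + noise_sd·ε` (defaults
loading 0.5, residual sd √(1−0.5²), so unit marginal variance), then scaled
to realistic units (mean curvature ~0.11/mm, volume ~9000 mm³, etc.). In
the MCI group every feature of each affected region is shifted *down* by
`effect_size` pooled standard deviations (default 3 sd in 5 of 76 regions),
emulating atrophy-driven loss of curvature and volume. What the generator
does **not** emulate: cortical folding geometry, spatially correlated
noise across neighbouring regions, site/scanner effects, or the
demographic covariates of real cohorts — so passing tests demonstrate the
machinery recovers planted effects under the stated model, not clinical
performance. With the default 3-sd effect the cross-validated accuracy is
near 100%; real NC/MCI separations are far smaller.

# Numerical choices and edge cases

* Histogram bins: 64; isovalue deterministic for fixed input and bins.
* Whitened-SVD CCA rank threshold 1e-10 of the leading singular value;
  conditional ridge 1e-8·trace/p; canonical-transform signs fixed
  deterministically (largest-magnitude Wx element positive).
* Platt calibration: BFGS on the smoothed-target likelihood, initialized at
  Platt's recommended point; probabilities clamped away from exp overflow.
* RBF bandwidth heuristic 1/(d·var); polynomial degree 3; C = 1 — all
  exposed as arguments and recorded in the fitted model.
* Fold assignment, inner-CV folds, phantom noise and cohort draws all take
  explicit integer seeds; no hidden global RNG state is consumed.
* Degenerate inputs: constant volumes refuse an isovalue; open meshes
  refuse a volume (reporting the boundary-edge count); constant feature
  columns normalize to 0.5 with a warning; empty regions and thin regions
  (<10 vertices) propagate as flagged missing values, never silent zeros.
* Umbilic points (λ₁ = λ₂): principal directions are an arbitrary
  orthonormal tangent pair; downstream code must not rely on them there.

# Problem sizes used in the shipped checks

The package's validation uses a 64³, 1 mm ball phantom of radius 10 mm
(≈5,700 vertices) and slab/cube/two-blob phantoms of similar size; the
cohort checks use the 60/86 design with 76 regions, 10-fold
cross-validation, a 3-permutation chance control and 20 simulation repeats
for the effect-localization audit. These sizes were chosen so the full
suite exercises every stage at the study's stated conditions while staying
comfortable on a single CPU.

# Known limitations

* The tetrahedral marching variant produces ~2× denser meshes than the
  cube-table variant; no decimation or smoothing is applied (the modelled
  pipeline performs none).
* Curvature defaults target ~1 mm isotropic voxels and cortical-scale
  structures; strongly anisotropic voxels will bias the quadric fit.
* The atlas-dilation labelling rule assigns boundary vertices to the
  nearest region greedily; vertices deep in background stay unlabelled.
* The two-layer classifier is trained per cohort; no transfer across
  normalization statistics or chains between cohorts is supported.
* sMCI vs pMCI discrimination is out of scope.
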