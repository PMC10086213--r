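---
title: "Methods: histology-MRI co-registration, the TRE protocol, and habitat clustering"
author: "HistoMRIfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histology-MRI co-registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HistoMRIfuse)
```

This vignette documents the models, conventions, default parameters and
design decisions behind the package, and states what the synthetic phantom
does and does not demonstrate about real data.

## Coordinate conventions

All geometry lives in world millimetres with NIfTI RAS semantics: the world
position of zero-based voxel index $i$ is
$\mathrm{origin} + D\,(s \circ i)$, where $D$ is the orthonormal direction
matrix and $s$ the voxel spacing. Voxel *centres* carry the coordinates, so
index $(0,0,0)$ sits exactly at the origin; this makes resampling
unambiguous. 2D sections use the same convention in-plane: pixel $(0,0)$ at
0 mm, centres every `pixelSize`. Every transform (rigid, thin-plate-spline)
operates on world millimetres, never on voxel indices, so histology pixel
sizes and MRI spacings interoperate without unit juggling.

Rigid transforms are stored as a JSON 4×4 homogeneous matrix (row-major)
with `fixed_space`/`moving_space` tags — the minimal self-describing form
for an alignment that must survive between processing sessions.

## Rigid ex vivo to in vivo alignment

The specimen's pose in the agarose block is arbitrary, so the first ex vivo
scan must be aligned to the in vivo scan before any sectioning decision. In
clinical practice this alignment is often done interactively; the package
replaces it with the deterministic closed-form least-squares fit on paired
landmarks (Kabsch): centre both point sets, take the SVD of the
cross-covariance $H = X_c^\top Y_c$, and set $R = V\,\mathrm{diag}(1,1,d)\,U^\top$
with $d = \mathrm{sign}\,\det(VU^\top)$, which corrects a reflective
optimum to a proper rotation. Only rotation and translation are estimated —
no scaling — matching the physical situation of a fixed specimen. Fewer
than 3 pairs or a collinear configuration (rank $<\,$2 after centering) is
refused by name. Intensity-based refinement (e.g. mutual information) is
deliberately out of scope: landmark-driven alignment is deterministic and
directly testable against ground truth.

## Cutting angles by virtual back-rotation

Trimming the block so that horizontal cuts reproduce the in vivo axial
planes requires the *back-rotated* sectioning normal
$n = (R_{\mathrm{ang}} R)^{-1} e_z$, where $R$ is the fitted rigid rotation
and $R_{\mathrm{ang}}$ an optional angulation of the original in vivo
acquisition (the composition implements the angulation correction). The
angle plate is described by:

- **elevation** — angle between $n$ and world $z$, computed as
  $\operatorname{atan2}(\lVert n_{xy}\rVert, n_z)$, which is numerically
  stable at both poles (an `acos` of the dot product loses half the
  floating-point digits near 0° and 180°);
- **azimuth** — direction of the tilt, $\operatorname{atan2}(n_y, n_x)$,
  counter-clockwise from world $+x$, reported in $[-180°, 180°)$. No
  convention is universal here; this one is documented and round-trips;
- **in-plane** — the residual rotation about $n$, extracted from
  $P^\top B$ where $P = R_z(\mathrm{az}) R_y(\mathrm{el}) R_z(-\mathrm{az})$
  is the plate rotation. Planar trimming needs only elevation and azimuth;
  the third angle is reported because a plate with three degrees of freedom
  can use it, and discarding it would lose information.

Degeneracies are resolved deterministically: at elevation 0 the azimuth is
reported as 0; an exactly antipodal normal ($n = -e_z$) yields the same
unoriented planes as elevation 0 and is reported as such. The module's
central correctness oracle — re-applying $P$ to $e_z$ must reproduce $n$ to
$<10^{-9}$ rad for arbitrary rotations — is enforced in the test suite with
the stable angle metric $2\arcsin(\lVert a-b\rVert/2)$.

Slice positions on the 4 mm localizer grid are slice *centres*, offset
spacing/2 from the block face, count $\lfloor \mathrm{extent}/\mathrm{spacing}
\rfloor$; whether grid lines mark centres or boundaries is a convention the
hardware leaves open, and centres make the first and last slice symmetric.

## Thin-plate-spline elastic registration

The histology-to-MRI-slice warp is a 2D thin-plate spline with kernel
$U(r) = r^2 \log r$: the unique minimum-bending-energy interpolant of the
control landmarks. "Nonrigid elastic" registration is a model class, not a
single model; the TPS is chosen because it is the canonical landmark-driven
elastic map, it interpolates its controls exactly at $\lambda = 0$ —
which the split-based accuracy protocol assumes — and it reproduces affine
maps with zero bending. The regularization $\lambda \ge 0$ (default 0) is
exposed for noisy landmarks; the control-point residual is non-decreasing
and the bending energy non-increasing in $\lambda$ (tested).

Image resampling uses the *inverse* warp so every target pixel pulls from a
well-defined source location; the inverse is approximated by fitting the
swapped-direction TPS on the same controls. This is exact for affine warps
and accurate at the smoothness scale of section deformations; it is cheaper
and more deterministic than numerically inverting the forward map per
pixel. If the fitted inverse folds (negative Jacobian determinant at more
than 1% of pixels) a warning is raised and the folding fraction recorded —
folding indicates landmarks inconsistent with a diffeomorphic deformation,
which the user should see but which need not abort a batch run.

## The random-split TRE protocol

Accuracy is measured without circularity by splitting the 30–40 landmark
pairs of a section at random into a registration half and an evaluation
half (disjoint by construction, asserted per iteration), fitting the TPS on
the first and recording Euclidean distances on the second, 100 times, then
pooling all distances. Choices the protocol fixes:

- split fraction 0.5 (symmetric, information-balanced); an odd landmark
  count gives the registration set the extra point;
- distances from all iterations are pooled before median/IQR;
  per-iteration medians are retained in the result object;
- quantiles are linear-interpolation (type 7);
- a fit failure aborts only its iteration; more than 10% aborted
  iterations abort the protocol;
- only the elastic stage is refit per iteration — the rigid alignment is
  upstream of the section landmarks and does not participate in the split.

**What "exact recovery" can mean.** A thin-plate spline fitted to a random
*half* of the landmarks is the minimum-bending interpolant through those
samples; for a generic smooth deformation this differs between samples from
the deformation that generated them, so held-out error cannot reach machine
precision even without noise. The only deformation family recoverable from
*every* ≥3-point subset is the affine family (TPS affine reproduction).
The phantom therefore provides two deformation modes:
`deformation = "affine"` (rotation/scale/shear/shift scaled so the largest
in-field displacement equals `amplitudeMm`; default 3 mm), for which the
zero-noise protocol median is $<10^{-6}$ mm, and `deformation = "tps"`
(Gaussian control displacements on a coarse grid), for which recovery is
good but not exact — the test suite checks both behaviours.

**Noise calibration.** Landmark annotation noise is isotropic Gaussian per
axis, applied by default to the histology-side points (both-sides and
noise-free modes are available). With noise $\sigma$ the held-out distance
combines the evaluation point's own noise with the warp error induced by
interpolating the noisy registration landmarks; treating the two as
independent $\sigma$-contributions gives a Rayleigh distance with per-axis
scale $\sigma\sqrt{2}$ and median $\sigma\sqrt{2\ln 4} \approx 1.665\sigma$.
Monte Carlo confirms this is unbiased, with ±20% realization-to-realization
spread for a single 35-landmark section; the acceptance computation
therefore pools 8 phantom sections × 50 iterations (~6,800 distances),
where the pooled median sits within a few percent of the closed form. TRE
is also non-decreasing in $\sigma$ (checked at 0, 0.5, 1, 2 mm) and
invariant to global translation of both landmark sets.

Group comparisons mirror standard nonparametric practice for the right-
skewed TRE distributions: Kruskal–Wallis across groups, pairwise Wilcoxon
rank-sum with Bonferroni multiplication (capped at 1), significance at
0.05. TRE per tumor volume (mm/mL, reported to 3 decimals) gives a
scale-free accuracy figure comparable across specimens.

## Habitat clustering

Within the tumor ROI, each voxel contributes an 8-vector of co-registered
quantitative parameters: ADC; the IVIM triplet D*, f, fD*; and the DCE
parameters Ktrans, kep, ve and a fourth DCE channel that may be provided as
vp or as iAUC (both names are accepted on read and stored under the `vp`
slot — quantitative reporting pipelines use either). "Equal weighting" of
channels whose native units differ by orders of magnitude is implemented as
per-channel z-scoring — the standard way to make such channels
commensurable; the scaling parameters are retained so centroids can be
mapped back to native units. Clustering is plain k-means (Lloyd) with
k-means++ seeding, best of 10 restarts by within-cluster sum of squares,
all randomness through one seed; $k = 4$ by default, reflecting the four
histological patterns the method is designed to discriminate, with no
automatic $k$ selection. Spatial coordinates are never features — space is
used only to display the labels on anatomy (renumbered by descending
cluster size for determinism).

Per-region statistics are native-unit mean ± SD; regions with fewer than 2
voxels are flagged with SD 0. Cross-region comparisons use one-way ANOVA
per channel plus pairwise Welch t-tests (pooled-variance mode available for
textbook cross-checks) with Holm step-down adjustment and conventional
significance stars.

## The phantom: what it emulates and what it does not

Every generator is a pure function of its seed. The in vivo phantom is a
lobulated ellipsoid (mean-zero low-order angular modulation, so the
analytic ellipsoid volume matches the voxelized ROI within a few percent)
with smooth internal texture; default grid 56×56×40 at 1.5×1.5×2 mm — a
scaled-down specimen chosen so every stage runs in seconds while leaving
~6,000 ROI voxels, ≥500 per habitat. Landmarks sit on scaled copies of the
tumor margin, emulating contour-based anatomical annotation. The ex vivo
copy applies a recorded random rigid pose (default up to 30°, ±8 mm) and
an optional concentric shrink factor (0.8–1) modelling fixation shrinkage.
Section phantoms deform an extracted MRI slice by a recorded smooth warp
and add annotation noise to the histology-side landmarks.

Habitat map stacks partition the ROI into centroidal Voronoi blobs
(contiguous, size-balanced) and draw each voxel's channels independently
from per-habitat normal distributions at the package's reference means/SDs
for the four tissue patterns (cell-rich, sclerotic, myxoid, predominantly
myxoid); negative draws are clipped at 0 and counted. Channel independence
within a habitat is a deliberate simplification — only per-region means and
SDs are available as reference values, so no covariance is modelled.

Consequences worth stating plainly:

- **Clipping bias.** For channels whose SD is comparable to the mean (e.g.
  ve in the predominantly-myxoid habitat, 705.9 ± 724.7), clipping shifts
  the realized mean upward by a fixed amount. Sample moments therefore
  match the *clipped*-normal moments, and the 3-standard-error recovery
  check in the tests is computed against those; at ~500 voxels per habitat
  the distinction is within 3 SE of the nominal means as well, but it grows
  relative to SE as $\sqrt{n}$.
- **Intrinsic overlap caps agreement.** Under the reference parameters the
  four habitat distributions overlap substantially in standardized space:
  the population-level adjusted Rand index between the k-means partition
  and the generating labels is ≈0.79–0.80 (estimated at 4,000 balanced
  voxels and confirmed across 8 spatial phantoms, range 0.77–0.82).
  Recovered cluster centroids are likewise biased away from the generator
  means by assignment-boundary truncation — a property of k-means on
  overlapping mixtures, not an estimation error that more voxels cure. The
  package reports the measured ARI and centroid deviations as-is; a
  clustering agreement near 0.8 on this phantom is the *correct* result,
  not a deficiency of the optimizer (it is seed-stable to ±0.001 across
  clustering seeds).
- The phantom has no MR physics: no bias fields, no partial-volume mixing
  at habitat borders, no stain variability, no tearing/folding artifacts
  beyond smooth TPS deformations. Passing its recovery tests demonstrates
  the *algorithms* are correct and calibrated, not that real sections will
  reach the same accuracy.

## Numerical choices

- Trilinear (volumes) / bilinear (sections) interpolation for scalar data,
  nearest-neighbour for label volumes; out-of-field is 0 (label 0).
  Indices within $10^{-6}$ voxel of the grid boundary are snapped onto it,
  so coordinate round trips do not zero edge voxels.
- NIfTI geometry is written to the sform (code 2) with float64 data, so a
  write/read round trip preserves arrays bit-exactly and geometry to
  $<10^{-6}$ (pixdim is float32).
- Rotation distances use $\theta = 2\arcsin(\lVert R_1 - R_2\rVert_F /
  2\sqrt2)$, exact and stable down to machine epsilon.
- The TPS system is solved densely; side conditions ($\mathbf 1^\top W = 0$,
  $X^\top W = 0$) are validated to $10^{-8}$ on construction. Duplicate or
  collinear controls are rejected before the solve.
- Protocol problem sizes used by the tests and the acceptance script:
  100-iteration protocols on 35-landmark sections, 8-section pools for
  noise calibration, 500 random orientations for the plate-angle oracle,
  ~6,000-voxel map stacks for clustering — sizes chosen to make sampling
  error small relative to each tolerance while keeping a full run in well
  under a minute.

## Known limitations

Rigid alignment and the TRE protocol consume *given* landmark pairs;
automatic landmark detection and consensus annotation are out of scope, as
are DICOM ingestion, stain-specific color processing, fitting of the
diffusion/perfusion models that produce the parametric maps, and driving
the physical angle plate or cutting hardware. Whether a physical plate's
third input degree of freedom corresponds to the reported in-plane angle
depends on the hardware; the mathematics covers it either way.
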