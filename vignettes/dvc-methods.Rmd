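---
title: "Measuring trabecular bone strain with grid-based DVC: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring trabecular bone strain with grid-based DVC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trabdvc)
```

This vignette is the package's own account of its methods: what is being
computed, which knobs matter, which conventions were fixed where several
defensible ones exist, and what the synthetic validation does and does not
demonstrate about real data.

## 1. The measurement problem

In stepwise in situ compression, a trabecular bone specimen is imaged by
microCT in a reference state and again under one or more loads. Digital
volume correlation (DVC) recovers the 3D displacement field that maps the
reference onto the loaded image, and differentiates it into strain. The
global (grid-based) flavour implemented here represents the displacement
field by values at the nodes of a regular grid with nodal spacing NS
(voxels), trilinearly interpolated in between. NS is the resolution/precision
trade-off: larger NS averages more texture per unknown and is more precise
but spatially coarser.

The registration objective is the masked sum of squared grey differences
plus a smoothing penalty,

$$\Phi(u) \;=\; \sum_{x \in \mathrm{mask}} \big[f(x) - g(x + u(x))\big]^2
\;+\; \lambda\,\lVert L u \rVert^2,$$

with $L$ the per-axis second-difference (squared-Laplacian) operator on the
node grid. Small-strain theory is assumed throughout (the engine refuses
apparent strains of 20% or more), which matches stepwise loading of bone to
and slightly beyond yield.

## 2. Numerical design of the solver

Choices that materially affect accuracy, each fixed after explicit
comparison during development:

* **Affine null space.** $L$ contains only second differences, so every
  affine displacement field has zero penalty. Smoothing therefore cannot
  bias the mean strain of a uniform-compression experiment, no matter how
  large $\lambda$ is — which is what makes the virtual-deformation
  validation design meaningful.
* **Consistent linearisation.** Gauss–Newton uses the analytic gradient of
  the interpolant that defines the objective, not a pre-computed
  finite-difference gradient volume. With an inconsistent gradient the
  solver's fixed point is not the objective's minimum; on affine test
  fields this displaced the recovered strain by several percent.
* **Cubic moving-image sampling.** Trilinear sampling of the moving image
  produces the classic sub-voxel "S-curve" systematic error, which does not
  cancel when nodal displacements span less than one voxel period — e.g. a
  1% compression of a 64-voxel column. Catmull–Rom cubic convolution
  (default `interp = "cubic"`) reduces this bias by roughly an order of
  magnitude; `interp = "linear"` remains available for comparison.
* **Smoothing schedule and margins.** Registration proceeds from a
  doubled-NS warm start through an image-blur schedule (default sigmas 3
  then 1 voxel, applied to both images). Blurring uses mirror boundaries,
  which fabricate even-symmetric content at the volume faces and drag
  boundary-cell strains toward zero; during blurred stages the metric
  therefore ignores a margin of about $2\sigma$ voxels at each face.
* **Damped steps.** Each Gauss–Newton step is halved until the objective
  decreases; a step that cannot improve the objective is treated as arrival
  at a stationary point. Failure to converge within the iteration budget is
  flagged on the returned field, never silent.

The smoothing weight is dimensionless: the penalty is scaled by the ratio of
the data-term and penalty-term traces, so the same value behaves similarly
across image sizes. On zero-strain (repeated-image) pairs the reference
field is constant, so MAER decreases monotonically with the weight and a
sweep cannot bound it from above. Over the documented candidate sweep
{0.003, 0.01, 0.03, 0.1, 0.3} (`select_smoothing()`), the smallest weight
within 5% of the sweep minimum is 0.3, frozen as the default; affine
recovery is unaffected by construction.

## 3. Preprocessing conventions

8-bit conversion maps a stated window linearly to [0, 255] with half-up
rounding. Segmentation follows the common femoral-head recipe: Gaussian
filter with sigma 0.5 voxel truncated at 1 voxel, global threshold 110 GSV,
then despeckling. "Remove unconnected regions" is realised as keeping the
single largest 26-connected component. The ×0.5 resampling is a 2×2×2 block
mean — equivalent to linear interpolation at half-sample offsets,
isotropic, and exactly reproducible — with a slice-wise (`xy_only`) variant
for strict 2D bilinear behaviour; voxel size doubles (39 µm to 78 µm).

The registration mask ("external contour of the bone") is built by
morphological closing with a ball radius followed by cavity filling. The
closing radius must exceed half the widest marrow space to bridge it; it is
a configuration parameter with no claimed fidelity to any particular
commercial implementation, and for synthetic volumes that span the whole
box a radius of ~12 voxels at 39 µm gives a usable solid mask. The best-fit
sphere used to delimit femoral-head analysis regions is an algebraic
least-squares fit to boundary voxels refined by geometric Gauss–Newton.

## 4. Morphometry conventions

* **BV/TV** is a voxel count ratio.
* **Tb.Th / Tb.Sp** use the model-independent local-thickness (largest
  inscribed sphere) transform. Sphere centers are evaluated on a half-voxel
  lattice (2× upsampling) so even-width structures are not systematically
  thinned by a full voxel; values are diameters `2 × EDT distance`. On exact
  plate phantoms of 5 and 8 voxels the result is exact; on digitized curved
  phantoms the method reports the thickness of the *digitized* object,
  which sits up to about one voxel below the nominal continuous diameter
  because background voxel centers intrude at diagonal angles (an
  11-voxel-diameter digitized cylinder measures 9.7 voxels; the test suite
  freezes that expectation from a brute-force inscribed-sphere oracle).
  This systematic quantisation is inherent to voxel-center distance
  transforms and is documented rather than hidden.
* **Conn.D** derives from the Euler characteristic of the union of closed
  voxel cubes (vertices − edges + faces − cubes of the incident cubical
  complex), which realises 26-connectivity for bone and 6-connectivity for
  marrow, as `(1 − χ)/V`. The convention matters on thin structures and is
  stated because connectivity conventions are rarely reported.

## 5. Strain, invariants and reporting

Cell displacement gradients come from trilinear shape-function derivatives
evaluated at cell centers (equivalently, means of the four edge differences
per axis); nodal tensors are unweighted means of adjacent cells (all cells
are congruent), and boundary nodes — which average fewer cells — are
flagged. Shear components are tensor shears ($\varepsilon_{ij} =
\gamma_{ij}/2$); the CSV exporter can emit engineering shears. The von Mises
equivalent strain uses the deviatoric form
$\frac{1}{1+\nu}\sqrt{\tfrac12[(\varepsilon_{p1}-\varepsilon_{p2})^2 +
(\varepsilon_{p2}-\varepsilon_{p3})^2 +
(\varepsilon_{p3}-\varepsilon_{p1})^2]}$ with $\nu = 0.5$ by default (the
$\tfrac23$ prefactor convention); $\nu$ is exposed because the literature
is split. Principal compressive strain summaries report magnitudes, with
signs retained in the stored fields. Medians of even counts use the
midpoint. The yield threshold defaults to 10,000 µε, the conventional yield
strain of bone tissue, with strict inequality and equal node weighting (a
coverage-weighted variant was considered and rejected for reportability;
node counts are always printed alongside).

## 6. Uncertainty framework

Zero-strain studies treat any strain measured between repeated images as
error (zero reference). Virtual-deformation studies warp the reference by an
exactly known uniform compression — revealed voxels are filled with the
background grey by default, because a black fill creates sharp grey
gradients at the replaced boundary slices that inflate axial errors; the
black fill is retained as an option precisely to reproduce that artifact,
and the test suite checks that excluding boundary node layers reduces the
axial random error under black fill. Systematic/random errors are
mean/sample-SD (n−1) per component over kept nodes; displacement errors are
emitted in both µm and voxels. Boundary exclusion is counted in node
layers.

`ns_tradeoff()` recommends the smallest NS whose *measured* MAER is at or
below the acceptance threshold (default 1000 µε, one order of magnitude
below yield so that yielded tissue remains discriminable). A logarithmic
model $a + b\log(\mathrm{NS})$ is fitted and reported as a diagnostic of
the expected decay, but the recommendation itself is the empirical
threshold rule: with typical sweep values the log fit can predict slightly
above threshold at a spacing whose measured MAER is already acceptable, and
the measured value is the defensible basis.

## 7. What the synthetic generator does and does not emulate

The microstructure model is a thresholded Gaussian random field: white
noise smoothed to a correlation length (default 160 µm), cut at the
quantile yielding the target bone volume fraction. This reproduces
plate/strut mixtures at realistic scales, exact control of BV/TV (presets
0.177–0.257 span the osteoarthritic femoral-head range), cyst-like
spherical voids, locally densified sclerotic patches, partial-volume edge
blur (default sigma 0.8 voxel), and additive Gaussian imaging noise. The
binary threshold is calibrated in one step against the package's own
imaging chain, because edge blur plus despeckling otherwise shrink the
*re-segmented* fraction by about 0.02.

It does **not** emulate scanner physics (beam hardening, rings, polychromatic
spectra), anatomical femoral-head geometry, cortical shells, or spatially
correlated noise. Consequently, passing virtual-deformation recovery here
demonstrates that the algorithmic chain is unbiased and precise under known
deformation of realistic *texture*; it does not certify error magnitudes on
any particular scanner's images, which must be established per study with
zero-strain repeats — exactly what `zero_strain_study()` is for.

All generator randomness flows through one integer seed per call, with the
global RNG state saved and restored; outputs are bit-reproducible.

## 8. Problem sizes and fixed seeds used by the test suite

Chosen as the smallest sizes at which each property is meaningfully
exercised: unit fixtures at 64³ voxels with NS 16 (4³ nodes); the
virtual-deformation recovery checks at 128³ with NS 25, matching the
validation design (1% and 5% levels, ±10% tolerance, two boundary node
layers excluded); the nodal-spacing sweep at 104³ and 78 µm so that NS 50
still yields a 3³ node grid (at 100³ it degenerates to a single cell and
the NS-precision ordering is no longer observable); and a three-specimen
48³ cohort for the end-to-end pipeline. Seeds are fixed in the tests;
the acceptance script takes its seed on the command line.

## 9. Known limitations

* Strain lives on the DVC grid itself; no finer FE mesh is interposed
  between displacement and strain, so strain resolution equals NS.
* Local thickness carries the voxel-lattice quantisation described above.
* The contour mask is a plain closing: it does not reproduce any specific
  commercial masking tool.
* Sub-voxel bias, though reduced by cubic sampling, still dominates the
  error budget when total displacements are well below one voxel; the
  virtual-deformation tests quantify it at the study scales.
* Rigid pre-registration of repeated scans is out of scope: image pairs are
  assumed pre-aligned (synthetic pairs are generated aligned).
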