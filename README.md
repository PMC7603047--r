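# trabdvc

Full-field strain measurement in trabecular bone volumes by global digital
volume correlation (DVC), with the surrounding toolchain a stepwise in situ
compression study needs: microCT-style preprocessing, 3D bone morphometry,
displacement-to-strain differentiation, a zero-strain / virtual-deformation
uncertainty framework, and load-step strain statistics. A synthetic generator
of osteoarthritis-like trabecular microstructures (controllable bone volume
fraction, cyst-like voids, sclerotic patches, imaging noise) provides image
pairs with exactly known deformation, so every stage of the chain can be
validated against ground truth.

The package is aimed at bone biomechanics work where a specimen is imaged in
an unloaded and one or more loaded states and the question is *where and how
strongly the tissue deforms*: osteoarthritic femoral heads and other whole
trabecular structures whose heterogeneous microarchitecture (sclerosis,
cysts, low-BV/TV regions) makes excised-cube testing unrepresentative.

## The measurement model

A regular grid of nodes with nodal spacing NS (voxels; `NS x voxel size` in
µm) is overlaid on the reference image `f` and the deformed image `g`. The
nodal displacements `u` minimise

    sum_masked_voxels [ f(x) - g(x + u(x)) ]^2  +  lambda * || L u ||^2

where `u(x)` is interpolated trilinearly between nodes, `L` takes second
differences of the nodal field along each grid axis (so affine displacement
fields are penalty-free), and the moving image is sampled with Catmull–Rom
cubic convolution to keep sub-voxel interpolation bias low. The solver is
damped Gauss–Newton with a doubled-NS warm start and a coarse-to-fine image
smoothing schedule.

Displacements are differentiated into the six-component small-strain tensor
on the hexahedral cells of the same grid (trilinear shape-function
derivatives at cell centers, averaged to nodes), from which principal
strains `ep1 >= ep2 >= ep3` and the von Mises equivalent strain are derived.
Measurement precision is quantified on repeated scans (zero-strain test) and
on virtually deformed copies with known strain: per-component systematic and
random errors, and

    MAER = mean over nodes of (1/6) sum_c | measured_c - true_c |
    SDER = standard deviation over nodes of the same per-node average

Morphometry follows the standard definitions: BV/TV; Tb.Th and Tb.Sp by the
model-independent largest-inscribed-sphere (local thickness) method;
Tb.N = (BV/TV)/Tb.Th; Conn.D = (1 - chi)/V with the Euler characteristic
computed under 26/6 connectivity.

## Worked example

Generate a synthetic trabecular volume, measure its morphometry, compress it
virtually by 1% apparent strain, and measure the strain field back:

```r
library(trabdvc)

spec <- synth_spec(dims = c(64, 64, 64), target_bvtv = 0.20, seed = 3)
vol  <- generate_trabecular_volume(spec)
bone <- segment_bone(vol)                      # Gaussian 0.5 vox, 110 GSV, despeckle
morphometry(bone, region_box(dim(vol$data), vol$voxel_size, border = 2))
#> <morphometry> BV/TV 20.1%  Tb.Th 326 um  Tb.Sp 655 um  Tb.N 0.615 /mm
#>   Conn.D 0.23 /mm^3  (region 12.81 mm^3)

vd    <- apply_virtual_deformation(vol, deformation_uniform(-0.01))
grid  <- build_grid(dim(vol$data), vol$voxel_size, ns = 16)
field <- dvc_register(vol, vd$volume, grid)
field
#> <displacement_field> 4 x 4 x 4 nodes @ NS 16, max |u| 19.52 um,
#>   residual RMS 0.42 GSV, converged: TRUE

strain <- exclude_boundary_layers(differentiate_strain(field), 1)
summarize_strain(strain)
#> <loadstep_summary> 32 nodes: med |ep3| 9603 ue, 34.4% above 10000 ue
```

The recovered median principal compressive strain (9603 µε against the
10,000 µε applied) sits within the interpolation-limited accuracy of a
64³ desk fixture; on the 128³ validation volume the recovered mean axial
strain is within ~1% of the applied level (see below). `zero_strain_study()`
and `virtual_deformation_study()` produce the per-NS uncertainty reports,
`ns_tradeoff()` picks the smallest nodal spacing whose MAER stays one order
of magnitude below the 10,000 µε yield strain, and `run_pipeline()` chains
everything over a cohort of synthetic specimens and correlates strain
outputs with morphometry (Spearman, with both t-approximation and exact
permutation p-values).

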