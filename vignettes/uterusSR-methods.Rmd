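---
title: "From key-slice contours to surface-rendered uterine models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From key-slice contours to surface-rendered uterine models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uterusSR)
```

## The problem

Planning a fertility-preserving myomectomy requires knowing how many
fibroids a uterus carries, how large they are, and where each sits relative
to the endometrial cavity and the serosal surface — intramural fibroids lie
within the myometrial wall, subserosal ones protrude beyond the outer
surface, submucosal ones indent the cavity. Reading this off a stack of
sagittal T2-weighted MR sections demands practiced spatial reasoning. A
colored 3D surface model (uterine body red, endometrium yellow, fibroids
green) shows the same information at a glance. This package implements the
full desk-side pipeline that produces such models, plus the evaluation
arithmetic of the reader study that motivated it.

## Semi-automatic segmentation

The segmentation model is operator-in-the-loop. An operator traces closed
contours of each structure on sparse *key slices*; the machine reconstructs
the slices in between.

**Contours.** A contour is a closed simple polygon in slice-plane mm
coordinates (`contour()`). Rasterization uses the even-odd rule on voxel
centers; a center exactly on the boundary counts as interior. This single
convention fixes every pixel-count question in the package (an axis-aligned
10 mm square whose edges pass through voxel centers rasterizes to 11 × 11
voxels, not 10 × 10).

**Inter-slice interpolation.** Between two consecutive key slices the masks
are reconstructed by shape-based interpolation: each endpoint mask is
converted to a signed Euclidean distance field (negative inside, exact
anisotropic distances via the lower-envelope algorithm), the two fields are
blended linearly in the slice position, and the result is thresholded at
zero. For masks that overlap slice-to-slice — which successive sections of
any smooth organ do — this reproduces linear interpolation of the boundary
position to within a voxel. When a structure ends between key slices the
missing endpoint is replaced by a uniformly positive field (the other
field raised by its maximum interior depth plus half a voxel), which erodes
the structure linearly to extinction rather than cutting it off. Disjoint
cross-sections do *not* morph into each other; the blend simply vanishes
between them, which we consider the correct behavior for separate organs.

**Cross-direction correction.** The validation step is geometric, not
intensity-based: body and endometrium keep only their largest 26-connected
3D component, fibroid components below `min_fibroid_voxels` (default 5) are
discarded, and endometrium voxels outside the hole-filled interior of the
body are removed. Correction never adds a voxel. We deliberately realize
"checking from other image directions" as 3D connected-component and
nesting analysis rather than literal re-interpolation in orthogonal planes:
the operation described is validation, and 3D connectivity is the
orientation-free formulation of it.

Where structures overlap, labels follow the fixed priority
fibroid > endometrium > body, so a traced body contour may simply enclose
everything and still yield the right label map.

## Surface rendering

Meshes are extracted by marching cubes with the classic 256-entry
triangulation table. Binary masks are treated as a {0, 1} field with
isovalue 0.5, which puts vertices at cube-edge midpoints; every input is
padded by one below-isovalue layer so surfaces close at the volume border.
The corner-bit convention is fixed (interior = above isovalue), which makes
the resolution of ambiguous saddle configurations deterministic; the
watertightness guarantee (every edge shared by exactly two faces) is
enforced by property tests on dense random masks rather than by appeal to
any particular published table variant. Two marching-cubes implementations
that resolve saddles differently can legitimately disagree on such masks;
on smooth anatomy-like blobs our enclosed volumes agree with an independent
implementation to better than 1%.

Raw binary-mask isosurfaces carry a staircase: a voxelized 10 mm sphere
measures about 9% more surface area than 4πr², while its enclosed volume is
within 1% of the voxel count. Smoothing is therefore part of rendering:
`smooth_mesh()` implements Taubin's two-step shrink/inflate filter with the
uniform graph Laplacian, defaults λ = 0.5, μ = −0.53, 20 iterations. At
these defaults the sphere's area lands within 0.5% of analytic and the
enclosed volume moves by under 0.5%; topology (V, E, F) is untouched. The
defaults are our choice — the upstream procedure named no smoothing
parameters — and are exposed as arguments.

`assemble_scene()` renders the filled outer surface of the uterus (red),
the filled endometrial cavity (yellow), and each 26-connected fibroid
component as its own green mesh. Scenes export to ASCII PLY (per-vertex
color), ASCII STL, and OBJ+MTL.

## Fibroid characterization

Individual fibroids are 26-connected components of label 3. Size is
reported as voxel volume and as maximum diameter — the largest pairwise
distance between voxel centers in mm, computed exactly and verified against
a brute-force oracle. Anatomical type is decided by geometric rules of our
own design (the clinical taxonomy defines the categories but no published
algorithm): submucosal if the component dilated by one voxel touches the
endometrium; otherwise subserosal if more than `exterior_fraction`
(default 10%) of its voxels lie outside the hole-filled body; otherwise
intramural. The removal heuristic flags all submucosal and subserosal
fibroids plus intramural fibroids of diameter ≥ 25 mm (configurable), and
suggests a procedure by pattern: submucosal-only removals → TCR, any
subserosal removal → LAM, otherwise TLM. These rules echo the structure of
the study's gold standard (which contained one submucosal-only TCR case and
subserosal-bearing LAM cases) but are explicitly *not* clinical judgments;
the gold standard also contains one LAM case with a single intramural
fibroid that no geometric rule recovers.

## The phantom

Testing segmentation and rendering needs volumes with known truth, so the
package generates synthetic sagittal T2-like pelvic phantoms: an
axis-aligned ellipsoidal uterine body of intermediate intensity (default
semi-axes 45 × 32 × 38 mm), a nested hyperintense endometrial cavity
(18 × 7 × 22 mm), spherical hypointense fibroids with radii in the clinical
3-12 mm range, additive seeded Gaussian noise (σ = 8 on means
30/100/200/40 for background/body/endometrium/fibroid), on a
96 × 96 × 64 grid at 1.5 × 1.5 × 2 mm — 2 mm being a typical section
thickness for the volumetric T2 sequences this pipeline targets. Identical
configurations generate bit-identical phantoms.

Every fibroid's *realized voxel geometry* is validated against its intended
type, with margins that make the type recoverable: intramural fibroids must
stay inside the body even after one-voxel dilation (a fibroid grazing the
serosal surface is anatomically ambiguous and is rejected as a
configuration error), subserosal ones must have comfortably more than the
classifier's exterior fraction outside, submucosal ones must genuinely
intersect the cavity. `random_phantom_config()` places conforming fibroids
by seeded rejection sampling.

`simulate_key_slice_tracing()` emulates the operator: each structure's
anatomically filled region is contour-traced (marching squares at the 0.5
level, vertices at pixel-edge midpoints) on every slice whose index is a
multiple of the step, plus the structure's last occupied slice. With no
jitter these contours rasterize back to the traced regions exactly, so
dense tracing reproduces the truth voxel-for-voxel — the identity that
anchors the segmentation tests. Optional jitter adds smoothed seeded radial
noise (in mm) to the vertices to mimic hand tremor.

What the phantom does *not* emulate: Rician noise statistics, coil
inhomogeneity, partial-volume fading, peristalsis artifacts, irregular
organ shape, or fibroid degeneration. Passing tests on phantoms therefore
demonstrates the correctness of the geometry pipeline, not clinical
segmentation accuracy on patient data.

## Reader-study arithmetic

The packaged 10-case study table (gold-standard procedure and per-type
removal counts; two observers' procedure and count readings from sagittal
and from surface-rendered images; required-time and difficulty summary
statistics) is shipped as checksummed JSON. `make_table4()` recomputes all
eight concordance rates — the study's accuracy measure is exact agreement
with the gold standard. `t_test_from_summary()` implements the unpaired
t test from group summary statistics; the pooled-variance (Student) form is
the default because it reproduces the study's published two-decimal
p values (0.53 and 0.28 for the difficulty scores) from the printed
mean ± SD, which is also evidence that those p values were computed on this
route; Welch's form is available as an option. p values from rounded summary
inputs are themselves compared at two decimals in the tests.

## Numerical choices and conventions

* Grid: 0-based voxel indices, voxel centers at `origin + index * spacing`,
  slice axis third; orientation metadata beyond spacing/origin is
  normalized to identity with a warning.
* In-plane pixel spacing is never hard-coded; it always comes from the file
  header or the explicit configuration.
* Dice of two empty masks is 1 (perfect agreement), Hausdorff 0; one-sided
  emptiness gives Dice 0 and infinite Hausdorff. Hausdorff distances are
  computed between voxel centers, against the 6-neighborhood boundary of
  the other mask (exact, since the nearest foreign voxel to an outside
  point is always a boundary voxel).
* Mesh orientation is normalized so the total signed volume is positive
  (outward normals).
* Problem sizes in the shipped tests and the acceptance script — the
  default 96 × 96 × 64 phantom, five randomized six-fibroid phantoms, a
  radius-10 sphere at unit spacing — were chosen as the smallest grids on
  which all geometric tolerances are meaningful; the whole suite runs in a
  few minutes on one core.

## Known limitations

* Convergence of segmentation accuracy with tracing density is monotone in
  the large (Dice rises from ~0.88 at a 10-slice step to 1.0 at dense
  tracing) but not strictly monotone step-by-step: key slices sit at index
  multiples of the step, so neighboring steps can align differently with a
  structure's first and last occupied slices. Tests assert monotonicity
  across well-separated steps (10, 5, 2, 1).
* Slices before the first key slice of a structure are left empty by
  design; a structure's leading cap can be missed by up to `step − 1`
  slices.
* The interpolator never splits or merges components within a gap; a
  structure that branches between key slices needs a key slice at the
  branch.
* DICOM series import is not included; convert to NIfTI upstream.
* PLY export is ASCII only.
* The removal/procedure suggestions are geometric surrogates for clinical
  decisions and must not be used as such.
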