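---
title: "Methods: 3D lesion measurement by constrained ellipsoid fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D lesion measurement by constrained ellipsoid fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionfit3d)
```

## The measurement problem

Prostate MRI reports lesion size from axial 2D measurements: the radiologist
draws regions of interest (ROIs) slice by slice, reads the maximum diameter
off the axial slice that best shows the lesion, and (in research settings)
estimates volume by planimetry — summing per-slice areas and multiplying by
the slice profile. Both numbers are blind to the through-plane direction: a
lesion whose long axis is oblique to the axial plane has a true maximum
diameter larger than any axial chord, and clinical acquisitions with 3 mm
slices separated by a further 3 mm gap sample that direction very coarsely.
The PI-RADS v2.1 assessment makes this consequential: a maximum diameter of
1.5 cm or more is the size criterion separating score 4 from score 5.

`lesionfit3d` measures the stacked 3D ROI volume directly. An ellipsoid is
fitted to the lesion surface, the tumour maximum diameter (TMD) is the full
major axis `2a` — in whatever 3D direction it points — and the tumour volume
(TV) is the ellipsoid volume

$$V = \tfrac{4\pi}{3}\, a\, b\, c ,$$

with `a >= b >= c` the principal semi-axes in mm (volumes reported in cc,
diameters in cm). The radiologist-style 2D measurements
(`planimetric_volume()`, `axial_max_diameter()`) are implemented alongside
so the two approaches can be compared subject by subject, and
`rescore_cohort()` applies the 1.5 cm criterion to quantify the clinical
impact.

## The constrained quadric fit

A general quadric is
$a x^2 + b y^2 + c z^2 + 2fyz + 2gxz + 2hxy + 2px + 2qy + 2rz + d = 0$.
Because quadric coefficients are homogeneous, least squares needs a
normalization; `fit_quadric()` uses the ellipsoid-specific constraint

$$kJ - I^2 = 1, \qquad
I = a + b + c,\quad J = ab + bc + ac - f^2 - g^2 - h^2,$$

with `k = 4` by default. Any coefficient vector on the positive side of this
constraint describes an ellipsoid, so the minimizer cannot be a hyperboloid
or paraboloid even on noisy, partial data. The solve is non-iterative:
the 10-column design row per point is
`(x^2, y^2, z^2, 2yz, 2xz, 2xy, 2x, 2y, 2z, 1)`; the four linear/constant
coefficients are eliminated in block form, leaving a 6x6 generalized
eigenproblem whose constraint matrix is the quadratic form of `kJ - I^2`
(diagonal `(-1,-1,-1,-k,-k,-k)`, with `(k-2)/2` on the pairwise `(a,b)`,
`(a,c)`, `(b,c)` entries). Among real eigenvectors on the positive side of
the constraint the one with the smallest algebraic residual is kept, and the
returned coefficients are rescaled so `kJ - I^2 = 1` exactly.

Numerical conditioning: raw mm^2 design columns are badly scaled, so the
point cloud is centred on its centroid and divided by its RMS radius before
fitting, and the transform is inverted on the recovered coefficients. The
constraint's sign survives both the rigid motion and the scaling, so the
admissibility decision is made in either frame. Determinism: the geometric
conversion (`quadric_to_ellipsoid()`) sorts axes by descending length,
orients each eigenvector so its largest-magnitude component is positive, and
flips the minor axis if needed to keep the rotation right-handed, so
identical input yields identical output.

### Applicability domain

`k = 4` guarantees an ellipsoid for "comparable" semi-axes, and that phrase
has a sharp meaning: the true quadric of an ellipsoid with semi-axes
`(A, B, C)` satisfies `4J - I^2 > 0` only when
`2(pq + qr + pr) > p^2 + q^2 + r^2` for `p = 1/A^2` etc. Strongly unequal
axes (for example 20:10:5, or 18:12:7) fall outside this domain, and the
constrained fit then returns the nearest admissible ellipsoid rather than
the generating one — by construction, not by numerical failure. The helper
`ellipsoid_constraint_value()` evaluates the boundary; exact-recovery tests
sample shapes inside the domain, which is the method's stated scope.
Interestingly the 15:10:6 shape used in the round-trip validation sits
exactly on the boundary (`4J - I^2 = 0` to machine precision) and is still
recovered well, because voxelized inputs never demand the exact limiting
quadric. A `k` larger than 4 admits more elongated shapes at the cost of a
weaker ellipsoid guarantee; values below 4 are rejected.

## Slice geometry, interpolation and what the fit actually samples

A clinical stack with 3 mm slice thickness and 3 mm gap has slice *centres*
6 mm apart; the package calls this sum the slice profile, the same factor
planimetry multiplies areas by. `interpolate_z()` converts such a stack to
contiguous fine slices (1 mm by default) by shape-based interpolation: each
slice becomes a 2D signed Euclidean distance map (negative inside, exact
distances to the contour-pixel centres, anisotropic in-plane spacing
honoured), the map is interpolated linearly along z between slice centres,
and a resampled voxel is inside where the value is non-positive. Original
slice centres reproduce their ROIs exactly. Beyond the first and last
occupied slice the end shape is held for half a slice profile (3 mm at
defaults): every slice is treated as representing its full 6 mm slab,
consistently with the planimetric volume. (Extending by only half the
*thickness*, 1.5 mm, systematically shortens lesions: a 10 mm-radius sphere
phantom then loses about 20% of its volume through the fit, which is why the
profile-half convention is the default.)

The ellipsoid is *not* fitted to resampled voxels. Between 6 mm-spaced
centres, linear interpolation of signed distance draws straight flanks where
a convex lesion really bulges, and holding end slices produces cylindrical
stubs with flat caps; surface points sampled from those regions are
artefacts of the kernel, not measurements, and on coarse stacks they
dominate the least squares (all sampling/extension variants of that pipeline
mis-measured the validation phantoms by 15-50%). Instead
`fit_sample_points()` collects what was actually observed: sub-pixel contour
points of every *measured* slice (midpoints of exposed pixel faces, which
straddle the true contour symmetrically and so carry no half-pixel inward
bias), plus two extent poles half a slice profile beyond the end-slice
centroids — the same slab convention as above, now expressed as two points
rather than two fabricated cap discs. The slice-to-slice change of the
contour rings carries the surface curvature; the poles pin the through-plane
extent. On already-fine grids every 1 mm slice contributes a ring and the
two conventions agree.

Masks occupying a single slice are refused by `fit_ellipsoid()`
(`insufficient_data`): one ring plus a convention determines no 3D shape
worth reporting. The hardest resolvable case is a lesion centred midway
between two slices so that exactly two equal rings are seen; the fit then
leans entirely on the poles and can under-read the major axis by ~10-15%.
That alignment sensitivity is a property of 6 mm sampling, not of the
solver.

## 2D reference measurements and report conventions

`planimetric_volume()` is area-sum x slice profile on the original grid
(exactly linear in both factors). `axial_max_diameter()` selects the
largest-area axial slice (ties: lower index) and returns the maximum
pairwise distance between inside-pixel centres, computed exactly over the
convex hull; sub-pixel edge extent is deliberately ignored, and a
single-pixel slice reports 0 with a degenerate-measurement warning. Reports
round cm/cc to 2 decimals and percentages to integers, halves away from
zero (`round_half_away()`); full precision is kept in returned objects and
JSON.

## PI-RADS rescoring semantics

`apply_size_criterion()` assigns score 5 when TMD >= 1.5 cm (inclusive, the
guideline's wording) and never downgrades. By default both score-3 and
score-4 lesions are eligible — the behaviour observed in the published
cohort this package validates against, where initially score-3 lesions with
large 3D diameters were reclassified 5 — while `upgrade_from = 4` gives the
strict guideline reading in which the size rule formally separates only 4
from 5. Cohort percentages use caller-supplied whole-cohort denominators
because published rescoring tables often list only the subjects whose score
changed.

## Agreement statistics

Between-method comparisons use the standard toolkit: paired two-sided t
(zero differences defined as t = 0, p = 1), Pearson correlation (undefined
for constant input — an error, not NA), Bland-Altman bias with
`bias +/- 1.96 * SD` limits, and Lilliefors-form Kolmogorov-Smirnov
normality (sample mean/SD estimated, via `nortest::lillie.test()`). All SDs
are sample (n-1) SDs. The absolute relative percentage difference of two
method means uses the *automated* mean as denominator; that choice is not
arbitrary — it is the only simple denominator consistent with the published
per-score pairs this package reproduces (e.g. manual 0.73 vs automated
1.36 cm gives 46%). Two of the published integers are not reproducible from
the printed summary means under any denominator: the score-3 TV pair
(0.36, 0.49) yields 27% where 26% was printed, and the score-5 TV figure of
17% matches a 1.12 cc mean printed elsewhere in the same source rather than
the 1.05 cc tabulated value; the packaged summary stores the tabulated
values and these discrepancies are simply documented. The published score-4
TMD difference (34%) appears to be a per-patient computation on data that
was never printed, and is likewise out of scope.

## The synthetic cohort generator

`simulate_cohort()` exists so every stage is testable without patient data.
Per subject it draws a true TV from a per-score lognormal (moment-matched to
the published automated-fit means/SDs: 0.49 +/- 0.31, 0.99 +/- 0.58,
1.05 +/- 0.78 cc — positive support and right skew are the natural model for
lesion volumes), axis ratios `b/a, c/b ~ U(0.6, 0.9)` (moderately triaxial,
like the drawn lesions), a major-axis tilt uniform on 0-60 degrees so the
axial measurement genuinely misses the major axis in a known fraction of
subjects, and a uniform sub-voxel/sub-slice placement offset. The phantom is
voxelized on the DWI-like grid (2.6 x 2.6 mm in-plane, 3 mm slices + 3 mm
gap; lesions in the validated cohort were drawn on DWI) and then measured by
the same code paths a real mask would take: `auto_*` from `fit_ellipsoid()`,
`manual_*` from `axial_max_diameter()`/`planimetric_volume()`. The manual
columns therefore exhibit the 2D under-reading *mechanism* (axial slicing +
tilt) rather than an assumed bias.

Two re-draw rules keep the generator honest on a gapped grid. A mask that
would occupy fewer than two slices is first re-centred midway between slice
centres (the multi-slice-visible lesions a radiologist would score); if the
drawn *shape* still cannot span two slices, the shape (never the volume) is
re-drawn progressively more prolate and tilted; and in the rare tail
(about 1% at score 3) where the *volume* itself is below what any shape can
resolve on 6 mm centres, the volume is re-drawn — the simulated population
is defined as slice-resolvable lesions, and the induced shift in the mean is
a few tenths of a percent. What the generator does *not* model: observer
variability, irregular (non-ellipsoidal) morphology (available separately
via `perturb_blob()`), intensity or contrast, or inter-sequence differences.
Passing cohort tests therefore validate the measurement pipeline under known
geometry; they do not certify accuracy on irregular real lesions — the
`perturb_blob()` experiments show fit error growing with surface
irregularity, which mirrors the clinical observation that not all lesions
fit the ellipsoid model well.

## Problem sizes and tolerances used in validation

The test suite fits 50 exact-point ellipsoids (recovery < 1e-6 mm inside
the admissibility domain), round-trips sphere (r = 10 mm) and 15:10:6
phantoms on both clinical and 1 mm isotropic grids (tolerances 8%/15% and
5%/10% for TMD/TV), and simulates 200 subjects per score (per-score mean
automated TV within 3 standard errors of the configured mean; mean automated
TMD above mean manual TMD in every stratum). Phantom placements use a
generic quarter-profile offset where a symmetric placement would create
measure-zero tangencies. These sizes keep the full suite under a minute of
fitting work while leaving Monte-Carlo margins well clear of their
thresholds.

## Known limitations

* Through-plane accuracy is bounded by the acquisition: two-slice lesions
  rest on the extent convention, and the midway alignment can under-read
  TMD by ~10-15%.
* The k = 4 constraint cannot represent strongly unequal axis ratios; fits
  of such shapes are pulled toward the admissible region.
* The axial Feret diameter ignores sub-pixel extent and in-slice partial
  volume; the planimetric volume inherits the slice-profile convention.
* Rescoring implements only the size criterion; signal-intensity components
  of PI-RADS scoring are out of scope.
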