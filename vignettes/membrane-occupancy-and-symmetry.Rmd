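---
title: "Quantifying membrane curvature, coat occupancy and cyclic symmetry from cryo-ET volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane curvature, coat occupancy and cyclic symmetry from cryo-ET volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memcurve)
```

memcurve implements the quantitative image analyses used to characterize how
membrane-remodeling protein assemblies (ESCRT-III-family proteins such as
Vipp1, which form rings, rods, tubes and extended membrane-bound carpets)
interact with membranes in cryo-electron tomograms and cryo-EM
reconstructions. This vignette is the package's account of the methods: the
models, the parameters that matter, what the synthetic scenes do and do not
emulate, and the numerical choices behind the implementation.

## Coordinate and unit conventions

All positions are physical Angstrom at voxel centers:
`physical = origin + index * voxel_size`, 0-based indices, x the fastest axis
(matching both the MRC data layout and R's column-major arrays). Curvatures
and curvedness are reported in 1/nm even though positions are Angstrom: the
biologically relevant regime (vesicles tens of nm across) then falls in the
convenient range 0.01-0.1, and the conversion (1/nm = 10/Angstrom) happens at
exactly one point, inside `estimate_curvature()`. Orientations are ZYZ Euler
angles in degrees rotating the reference +z axis onto the membrane normal;
the third (in-plane) angle is unconstrained by a normal and defaults to 0,
matching the role of these angles as priors that restrain only the
out-of-plane part of an angular search.

## Membrane surfaces and curvedness

Segmented tomograms arrive as integer label volumes (background, membrane,
coat, ribbon). Cleanup removes, per class independently, 26-connected
components smaller than 150 voxels -- strictly: a 150-voxel component
survives, because the rule is "islands of fewer than 150 voxels".
26-connectivity is used because membrane segmentations are thin shells that
6-connectivity would fragment.

`extract_surface()` samples the 0.5 level of the Gaussian-smoothed
(sigma = 1 voxel) binary class mask. Boundary voxels seed the point set and
each seed is moved along the local field gradient to the level crossing by
bisection, giving positions accurate to a fraction of a voxel; normals are
the negated normalized gradient, which for closed components points away from
the enclosed interior automatically. Points within `edge_margin` (default
50 Angstrom, deliberately equal to the coat-proximity threshold so that
boundary artifacts cannot masquerade as coat signal) of any volume face are
flagged and later excluded.

Curvedness is the Koenderink measure `C = sqrt((k1^2 + k2^2)/2)`: `1/r` on a
sphere of radius r, `1/(r*sqrt(2))` on a cylinder, 0 on a plane.
`estimate_curvature()` obtains the principal curvatures from a Monge-patch
fit in each point's normal-aligned frame. Three design choices matter for
accuracy on voxelized data, and all three were driven by the analytic-surface
oracles (rasterized spheres, cylinders and slabs with known curvedness) that
define conformance for any estimator here:

* **Quartic height fit.** A pure quadric folds the higher-order shape of a
  sphere into its curvature term (a bias growing with (patch/r)^2). The fit
  therefore includes full cubic and quartic terms -- which absorb that shape
  exactly for spheres and cylinders -- while only the quadratic coefficients
  enter the shape operator. Small neighborhoods (< 25 points) fall back to
  the quadric.
* **Same-face gating.** Membrane shells have two faces a few voxels apart.
  Neighbors whose normal disagrees with the center point's normal
  (dot <= 0.2) are excluded, so the faces never mix in one fit and the
  neighborhood radius can exceed the shell thickness.
* **Invariant averaging.** Per-point fits carry zero-mean noise from
  voxelization. Averaging sorted principal curvatures, or taking
  `sqrt(k1^2 + k2^2)` per point, turns that noise into a positive curvedness
  bias. Instead the mean curvature H and Gaussian curvature K -- both smooth
  functions of the shape tensor -- are averaged over the neighborhood, and
  curvedness is formed afterwards as `sqrt(2*H^2 - K)`.

The default neighborhood radius is 4.5 x the point spacing: large enough for
the averaging to suppress voxelization noise, small enough (with the normal
gate) to stay local. With these choices the oracles recover curvedness
within about 2-3% down to sphere radii of 10 voxels; the package's tests
enforce 5%.

## Coat occupancy versus curvedness

A membrane surface point is *proximal* when its Euclidean distance to the
nearest coat-voxel center is at most 50 Angstrom (point-to-voxel-center
rather than point-to-voxel-surface: simpler, uniform, and different by at
most half a voxel diagonal). Points are sorted into fixed-width curvedness
bins (default 0.004 1/nm, giving ten bins across the 0.02-0.06 1/nm regime
of interest) and each bin's occupancy is the fraction of its points that are
proximal, a number between 0 (no coverage) and 1 (full coverage).

`fit_saturation()` quantifies the transition from curvature-dependent binding
to saturation with a continuous two-segment model -- a line up to a
breakpoint c\*, constant beyond -- fitted by weighted least squares (weights
= bin counts) with the breakpoint chosen by a 1-D scan over bin edges
minimizing the residual sum of squares. Ties keep the smallest breakpoint,
so flat data report c\* at the range start and strictly linear data at the
range end. One bias is worth knowing about: real coverage data are
*flat-ramp-flat* (occupancy near zero below the binding onset), and the
two-segment model has no foot segment, so the fitted line tilts slightly and
the breakpoint lands up to one bin above the true saturation point. The
package keeps the two-segment form because it is the direct quantification
of "linear increase, then saturation", and reports the fitted zero-crossing
(`ramp_onset`) for orientation rather than as an onset estimate.

## Particle preparation

Subtomogram-style particle sets are seeded from the surface points:

* `enforce_min_distance()` thins to a minimal spacing of 15 Angstrom,
  greedily in input order (the extraction order); the result is separated
  and maximal -- every excluded point lies within 15 Angstrom of a retained
  one.
* `orientations_from_normals()` writes the ZYZ priors described above.
* `cluster_by_curvature()` partitions on the 1-D curvedness values with
  k-means (`stats::kmeans`, many restarts, seeded); labels are relabeled by
  ascending cluster mean so results are deterministic. The package's tests
  hold the partition cost to the exact dynamic-programming optimum for 1-D
  clustering.
* `filter_orientation_outliers()` excludes particles whose normal deviates
  by more than 30 degrees from the component-wise median normal of their
  neighbors within 100 Angstrom; particles with fewer than 3 neighbors are
  kept and flagged. Median rather than mean: a flipped normal in the
  neighborhood should not drag the consensus. The thresholds are package
  defaults -- the underlying idea ("exclude particles diverging from the
  local majority") does not prescribe them.

## Cyclic symmetry by self-correlation

The symmetry of a ring or patch density is determined by maximizing the
correlation between the map and symmetry-averaged versions of itself over
the order n, the axis offset d along x (1-Angstrom steps), and the rotation
about the axis -- a translational scan per candidate order first, then a
rotational scan at the best (n, d). The map is assumed pre-aligned with the
ring axis along z and the patch along +x (`rotate_map_z()` helps).

The score is evaluated on a cylindrical resampling about the candidate axis
(rings at voxel-size radial steps, 1-degree azimuthal steps, annulus-area
weighting; samples outside the grid count as zero after the map's ambient
median level is removed, which also makes the search invariant to global
scale and offset of the densities). Three refinements make the score usable
on noisy, partial data:

* the per-ring azimuthal mean (the axisymmetric component, invariant under
  every candidate symmetry) is removed, eliminating a lag-independent
  correlation baseline;
* the identity copy is excluded from the symmetry average: it carries the
  full voxel noise of the map itself and would otherwise bias the plain
  correlation toward small n as 1/sqrt(n);
* the correlation is restricted to a data-driven mask -- rings weighted by
  their residual variance in excess of the median (the solvent floor,
  smoothed over the (r, z) neighborhood), and azimuths holding signal energy
  -- so an off-axis patch covering only part of a ring is compared where it
  has data.

`noise_robust = FALSE` gives the plain Pearson correlation of the map with
its full Cn average over the whole cylindrical domain, which matches
`map_correlation()` of the map with `apply_cn()` up to discretization and is
the right setting for clean, complete rings.

**Limitation.** On a partial patch, candidate parameters along the ridge
`d/n ~ const` produce nearly identical arc spacings, and for smooth,
feature-poor densities the orders n-1 and n+1 at rescaled offsets are close
to degenerate with the truth; discrimination comes from ring curvature and
radially extended features accumulating phase error across the patch. At
low voxel signal-to-noise (below roughly 4) adjacent orders can swap on such
patches. High-SNR averages with features near the resolution limit -- the
realistic input for this analysis -- are recovered reliably, and the
`low_confidence` flag marks searches whose best correlation stays below 0.4
(for instance when the true order lies outside the searched range).

## Tube and ring profiles

`radial_profile()` bins voxels by center radius about the z axis, so binned
totals conserve the slab density exactly; a center-of-mass drift of more
than 2 voxels across z triggers a misalignment warning. Leaflet radii are
the density maxima of the two bilayer headgroup peaks: the two innermost
peaks whose topographic prominence exceeds 10% of the profile's dynamic
range, refined by a two-Gaussian-plus-baseline fit. The refinement matters
when the headgroup peaks are broad: the local maxima of a sum of two broad
peaks sit closer together than the component maxima (for 15-Angstrom-wide
leaflets 35 Angstrom apart, by about 7 Angstrom), while the component fit
recovers each leaflet's own maximum; a single overly wide innermost peak is
recognized as a merged pair and split for initialization, with any outer
protein shell included as an explicit third component. Bilayer thickness is
the peak-to-peak separation.

The outer diameter is twice the outermost radius at which the density
crosses half the outermost qualifying peak (relative to the large-radius
background) on the outward side. `axial_leaflet_trace()` repeats leaflet
detection per axial slab and derives the narrowest/widest membrane diameters
and the kink angle at a constriction: the angle between straight-line fits
of r(z) over 30-60 Angstrom flanking windows on either side of the trace
minimum, excluding a small gap around the apex where the shell width rounds
the profile (180 degrees for a straight tube, by construction
`2*atan(1/slope)` for a conical hourglass).

## Synthetic scenes: what they emulate, and what they do not

`make_vesicle_scene()` renders vesicles as spherical membrane shells
(40 Angstrom thick, roughly a segmented bilayer) at 10 Angstrom voxels, with
protein-coat patches layered outside the shell. Each vesicle's coat area
fraction follows the linear-ramp coverage model
`clamp((C - 0.02)/(0.06 - 0.02), 0, 1)` evaluated at its true curvedness
(`10/radius` 1/nm), realized as up to 3 contiguous spherical caps --
contiguous patches, not independent voxel flips, because proximity labeling
behaves differently for loose coats and carpets than for salt-and-pepper
coverage. Two percent of membrane voxels are flipped to background as a
stand-in for segmentation error. Scene geometry is controlled by a separate
`geometry_seed`, so different noise seeds share identical ground truth.

`make_tube_map()` builds density maps as Gaussian annular shells at the two
leaflet radii and a protein radius, with optional additive noise and an
optional hourglass constriction. `make_cn_map()` places a multi-blob motif
(features spanning ~50 Angstrom radially -- a radially extended unit is what
makes the order of a partial ring identifiable at all) n-fold around an
offset axis, optionally restricted to a wedge emulating a subtomogram-average
patch cut from a larger ring.

The validation scenes use problem sizes that keep the full test suite in the
minutes range: 30 vesicles spanning curvedness 0.018-0.098 1/nm in a ~300^3
volume for the occupancy analysis; 20 symmetry patches over orders
{6, 12, 18, 20, 22} with offsets of 60-150 Angstrom, features of
sigma = 4 Angstrom (the half-width of features at an ~18-Angstrom resolution
limit), wedges of 150 degrees (300 for C6, so that several of the 60-degree
repeats are covered) and voxel signal-to-noise of 8, emulating
high-signal subtomogram averages; tubes with leaflet shells at 85 and
120 Angstrom (thickness 35 Angstrom) and leaflet widths of 5-15 Angstrom.

The generators deliberately do **not** simulate tilt-series acquisition: no
missing wedge, no contrast transfer function, no anisotropic resolution, no
spatially correlated segmentation errors, and label noise is a uniform
random flip rather than the structured errors a U-Net makes near ambiguous
density. Passing tests therefore demonstrate that the analysis chain
recovers known ground truth from idealized scenes with the statistical
structure the methods assume -- not that segmentation or reconstruction
artifacts of real tomograms are handled.

## A short worked example

```{r example, fig.width = 6, fig.height = 4}
scene <- make_vesicle_scene(10 / seq(0.02, 0.09, length.out = 8), seed = 1)
res <- run_occupancy(scene$labels)
res$fit
plot(res$profile, fit = res$fit)
```

The fitted breakpoint sits at the curvedness where coverage saturates; by
the sphere relation `d = 2/C`, a breakpoint near 0.06 1/nm corresponds to a
vesicle diameter of roughly 30 nm.
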