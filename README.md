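# memcurve

Quantitative image analysis of segmented cryo-electron tomograms and cryo-EM
density maps of membrane-remodeling protein assemblies — written for
structural biologists studying how ESCRT-III-family proteins (Vipp1/PspA-like
rings, rods, tubes and membrane-bound carpets) deform membranes, and for
anyone who needs curvature-resolved statistics from segmented volumes.

The package implements four analyses end to end:

1. **Coat occupancy versus membrane curvedness.** Membrane surfaces are
   extracted from label volumes as oriented point sets; per point, the
   principal curvatures k₁, k₂ are estimated by a local Monge-patch fit and
   summarized as the Koenderink curvedness

   C = √((k₁² + k₂²)/2)   (1/nm; C = 1/r on a sphere, 1/(r√2) on a cylinder).

   Points within 50 Å of the protein-coat segmentation are *proximal*;
   occupancy per fixed-width curvedness bin is the proximal fraction
   O(C) ∈ [0, 1]. A weighted two-segment fit (line, then constant; breakpoint
   c\* by 1-D scan) quantifies the saturation of coat binding: by the sphere
   relation d = 2/C, a breakpoint near 0.06 nm⁻¹ corresponds to full coverage
   of vesicles below ≈ 30 nm diameter.
2. **Subtomogram-style particle preparation.** Minimum-spacing enforcement
   (15 Å), ZYZ Euler orientation priors from membrane normals, k-means
   clustering on curvedness, and local orientation-consensus outlier
   rejection.
3. **Cyclic-symmetry determination.** The order n, axis offset d and rotation
   of a ring or off-axis patch density are found by maximizing the
   correlation of the map with symmetry-averaged copies of itself
   (translational scan in 1-Å steps for each candidate n, then a rotational
   scan), with a noise-robust masked score for partial, noisy patches.
4. **Radial/axial tube profiling.** Radial density profiles about the tube
   axis; bilayer leaflet radii at the headgroup density maxima (two-Gaussian
   refinement), thickness as their peak-to-peak separation; outer diameter at
   the half-maximum crossing; per-slice leaflet traces with the kink angle at
   a membrane constriction.

A synthetic-scene generator (`make_vesicle_scene()`, `make_tube_map()`,
`make_cn_map()`) produces label volumes and density maps with known ground
truth, so the whole chain is testable without any external data. I/O covers
MRC/CCP4 volumes (maps and segmentations) and TSV particle tables.

## Worked example

```r
library(memcurve)

# eight vesicles spanning curvedness 0.02-0.09 1/nm, coat coverage ramping
# between 0.02 and 0.06 1/nm
scene <- make_vesicle_scene(10 / seq(0.02, 0.09, length.out = 8), seed = 1)
res <- run_occupancy(scene$labels)
res$fit
#> <saturation_fit> occupancy = intercept + slope * curvedness, then plateau
#>   slope        21.083 per (1/nm)
#>   intercept    -0.356
#>   ramp onset   0.0169 1/nm (fitted zero-occupancy curvedness)
#>   breakpoint   0.0640 1/nm
#>   plateau       0.994
#>   weighted RSS 784 over 40 bins
```

The breakpoint (0.064 nm⁻¹, within one 0.004-nm⁻¹ bin of the generating
model's 0.06) is the curvedness where membrane coverage saturates at the
plateau (0.994 ≈ full coverage); `2 / 0.064 ≈ 31 nm` is the corresponding
vesicle diameter. The occupancy table behind the fit:

```r
subset(as.data.frame(res$profile), n_points > 0)
#>    curvedness_lo curvedness_hi n_points n_proximal occupancy
#> 7          0.024         0.028    13762       1338    0.0972
#> 10         0.036         0.040     6533       2963    0.4535
#> 13         0.048         0.052     4205       3143    0.7474
#> 16         0.060         0.064     2133       1954    0.9161
#> 19         0.072         0.076     1064       1054    0.9906
#> 22         0.084         0.088      886        886    1.0000
```

Symmetry of a noisy off-axis patch (a 150° wedge of a C20 ring, axis
offset 110 Å):

```r
g <- make_cn_map(n = 20, axis_offset = 110, patch_wedge = 150, blob_sd = 4,
                 noise_sd = 0.125, seed = 1, voxel_size = 2.5)
search_symmetry(g$map, n_range = 18:22, offset_range = c(90, 130))
#> <symmetry_result> best C20 at axis offset 110.0 A, rotation 17.5 deg (corr 0.812)
#>   C18  best correlation 0.615
#>   C19  best correlation 0.774
#>   C20  best correlation 0.812
#>   C21  best correlation 0.752
#>   C22  best correlation 0.646
```

Bilayer geometry of a membrane tube with leaflet shells at 85 and 120 Å:

```r
tb <- make_tube_map(85, 120, 150, leaflet_sd = 5, noise_sd = 0.05, seed = 3)
detect_leaflets(radial_profile(tb$map))
#> leaflets 85.3 / 120.6 A -> thickness 35.3 A
```

A thin command-line wrapper over the same functions lives in
`inst/cli/memcurve.R` (subcommands `simulate`, `occupancy`, `symsearch`,
`tubeprof`).

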