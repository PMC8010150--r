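# neosurf

Cortical surface reconstruction for neonatal brain MRI, in R.

Neonatal brains are small and weakly myelinated: on T1-weighted images the
white matter (WM) is darker than grey matter (GM), WM and CSF intensities are
similar, and — most damaging for surface extraction — the CSF inside deep,
narrow sulci often occupies no pure voxel at all. Standard adult pipelines,
which find the pial (GM/CSF) boundary by following visible CSF, then fuse
opposing sulcal banks and report cortex twice too thick. `neosurf`
reconstructs both cortical surfaces from a T1-like intensity volume plus a
tissue segmentation (background/CSF/GM/WM) while explicitly hypothesizing
where invisible sulcal CSF must be.

The geometric core, per hemisphere (or whole object for closed phantoms):

1. **Topology-guaranteed WM surface.** A filled ellipsoid enclosing the WM
   mask is collapsed onto it by removing only *simple points* (object
   26-connectivity, background 6-connectivity), so the result is homotopic to
   a ball no matter how many handles or cavities the segmentation has. Its
   voxel boundary is triangulated, smoothed (Taubin), coarsened by
   topology-safe edge collapse, inflated to a sphere, and resampled as a
   subdivided icosahedron: `20·4^L` triangles (level 6 → 81,920), identical
   vertex ordering for every subject.
2. **Skeleton of the GM∪CSF union.** Where sulcal CSF is invisible, its
   location is hypothesized as the medial surface of the GM∪CSF union:
   catchment-basin seeds are placed at sulcal fundi by thresholding the
   curvature of the WM boundary, and a curvature-gated *homotopic erosion*
   with an embedded watershed thins the union from the WM border outward.
   Fronts from opposing banks meet mid-sulcus, where voxels become
   non-simple and persist as the medial sheet; the brain-hull shell is
   pre-marked as the gyral part of the skeleton. Remaining voxels are
   classified into the nine digital-topology categories (interior, isolated,
   border, curve, curves, surface, surface-curve, surfaces, surfaces-curve)
   and deletable classes are pruned.
3. **Pial surface.** A harmonic potential φ (∇²φ = 0; φ = 0 at the WM
   boundary, φ = 1 on skeleton and hull) is solved on the union, and each WM
   vertex is advected along ∇φ until it reaches the skeleton or visible CSF.
   The arrival points, with WM connectivity, are the intermediate pial
   surface — a one-to-one, crossing-free WM↔pial correspondence. A
   short-range intensity-gradient refinement (1D profiles along vertex
   normals, maximum gradient re-scored by a surface-blurred target-intensity
   map, skeleton as a barrier, self-proximity constraints) then fits the
   actual GM/CSF edge.
4. **Morphometry.** Cortical thickness (linked / nearest / symmetric
   vertex distances), FWHM-calibrated surface smoothing (default 10 mm),
   sulcal depth against the brain hull, exact landmark-to-surface distances,
   and best-template selection by Pearson correlation of sulcal-depth maps.

Everything is testable without any imaging data: the built-in phantom
generator produces shell and folded-slab volumes with analytic ground-truth
surfaces, exact control of the sulcal gap (the invisible-CSF condition is a
parameter), partial-volume intensity synthesis and seeded noise.

## Worked example

Reconstruct surfaces on a folded-slab phantom whose two sulci have a 0.4 mm
CSF gap — under 1 mm voxels no sulcal CSF voxel survives labelling:

```r
library(neosurf)
spec <- phantom_spec("folded_slab", r1 = 20, r2 = 22, sulcal_gap = 0.4,
                     fold_amplitude = 10, fold_wavelength = 16, dim = 64)
result <- run_pipeline(pipeline_config(phantom = spec, level = 4, seed = 1))
result
#> <pipeline_result> 1 hemisphere(s)
#>   whole: 2562 vertices, mean thickness 2.15 mm, chi 2

result$hemis$whole$qa
#> # A tibble: 3 × 4
#>   stage      euler self_intersections vertices
#>   <chr>      <int>              <int>    <int>
#> 1 wm_extract     2                 NA    14356
#> 2 wm_refine      2                  0     2562
#> 3 pial           2                  0     2562

lm <- result$truth$sample_outer(100, seed = 1)
attr(landmark_distances(lm, result$hemis$whole$pial_surface), "mean")
#> [1] 0.3978164
```

The true bank thickness is 2 mm; the reconstruction reports 2.15 mm even
though the sulcal CSF is entirely invisible, every surface has Euler
characteristic 2 with zero self-intersections, and landmarks sampled on the
analytic pial surface lie 0.40 mm (under half a voxel) from the
reconstructed one. Surfaces are written as Wavefront OBJ, volumes as NIfTI;
`inst/cli/neosurf.R` exposes the stages (`phantom`, `wm-surface`,
`skeleton`, `pial`, `thickness`, `run`) as shell subcommands.

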