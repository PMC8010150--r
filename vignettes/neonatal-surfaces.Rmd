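---
title: "Reconstructing neonatal cortical surfaces: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing neonatal cortical surfaces: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`neosurf` reconstructs the white-matter (WM/GM) and pial (GM/CSF) cortical
surfaces of small, weakly myelinated brains from a T1-weighted-like intensity
volume and a co-registered tissue segmentation. This vignette explains the
models behind each stage, the parameters a user may want to touch, the
numerical choices that were genuinely open, and what the synthetic phantoms
do and do not establish about real data.

## The problem

Two properties of neonatal T1 images drive the design. First, contrast is
inverted and weak: unmyelinated WM is darker than GM, and WM intensity is
close to CSF. Second, partial volume effects are severe: the brain is small
relative to the voxel size, and the CSF inside deep, narrow sulci frequently
occupies no pure voxel — opposing sulcal banks appear fused in both the
image and the segmentation. A pial surface that only follows visible CSF
cannot enter such sulci and overestimates thickness there by up to the fold
depth. The package treats the segmentation as given (any tool may produce
it; codes are background 0, CSF 1, GM 2, WM 3, with a remapping table at
read time) and solves the downstream geometric problem.

## Stage 1: topology-guaranteed WM surface

The cortical mantle of one hemisphere is topologically a sphere, but
segmentations contain handles and cavities. Rather than repairing the mesh
afterwards, the topology is fixed by construction: a filled ellipsoid
enclosing the WM mask (bounding-box axes × 1.25 + 3 voxels) is eroded onto
the mask by a priority queue that removes the voxel farthest from the mask
first, and only when it is a *simple point* under the object-26 /
background-6 connectivity pair — removal then provably preserves connected
components, cavities and tunnels. Handles in the mask end up plugged and
cavities filled, and the result is homotopic to the ellipsoid, i.e. a ball.

The surface is extracted from the collapsed set directly as its voxel
boundary. Before triangulation the set is made *well-composed*: the critical
configurations (two diagonal object voxels in a 2×2 square, two antipodal
corners in a 2×2×2 cube) are repaired by adding voxels, each addition itself
a simple-point operation so topology is untouched. On a well-composed set
the voxel boundary is a 2-manifold whose genus equals the digital genus, so
the Euler-characteristic-2 guarantee is exact rather than resting on a
marching-cubes disambiguation table; the blocky geometry is then relaxed by
low-shrink Taubin smoothing (10 λ/µ pairs, λ = 0.5, µ = −0.53). This was a
deliberate design choice over marching cubes: binary marching cubes needs an
ambiguity rule consistent with the connectivity pair, and any mismatch
silently converts digital handles into mesh handles, which is the single
failure mode the stage exists to exclude.

Coarsening merges the two vertices of the currently shortest edge
(midpoint placement) only when the link condition holds and no incident
triangle flips, so closedness, manifoldness and Euler characteristic are
invariant; the default target before inflation is 30,000 vertices.
Inflation applies uniform Laplacian smoothing (step 0.6) until the umbrella
vector of every vertex points inward (a convexity proxy), projects to the
centroid-centered unit sphere, and relaxes tangentially until no spherical
triangle has negative signed area (flipped triangles would break point
location). Icosahedral resampling locates each vertex of a subdivided
icosahedron in the spherical triangulation (nearest-vertex bucket search
plus breadth-first walk; a nearest-triangle fallback handles degenerate
cases) and pulls its barycentric coordinates back to the original mesh.
Level L gives 20·4^L triangles and 10·4^L + 2 vertices — level 6 is the
conventional 81,920-triangle surface — with identical connectivity for all
subjects, which is what makes vertex-wise group analysis possible. The
default in the bundled pipeline is level 4 (2,562 vertices), matched to the
phantom grid sizes used throughout the tests.

## Stage 2: the GM∪CSF skeleton

Where sulcal CSF is invisible, its most defensible location is the medial
surface of the union of GM and CSF: under the assumption that the cortex has
locally equal thickness on the two banks of a sulcus, the GM/CSF interface
lies halfway between the opposing WM walls. The skeleton stage realizes
this:

* **Union and boundaries.** The union is GM∪CSF within the brain mask,
  extended by whatever the morphological closing of the brain mask adds
  (bridged sulcal mouths, rounded corners count as virtual CSF inside the
  hull). The *hull* — the boundary shell of the closing, default structuring
  radius 2 voxels — is pre-marked as skeleton: it is the gyral interface.
  The *internal border* is the set of union voxels 6-adjacent to WM.
* **Curvature.** Mean and Gaussian curvature are computed from the
  implicit surface of the Gaussian-smoothed (σ = 1.5 mm) indicator
  function, by central differences and the standard formulas; the sign
  convention is convex-outward positive (a ball of radius R has H = 1/R).
  Voxels with squared gradient below 10⁻⁴ have no locally defined surface;
  their curvature is zeroed and flagged, which also gates out the numerical
  noise the raw quotient produces in flat regions.
* **Seeds.** Catchment basins are internal-border voxels whose WM-surface
  mean curvature is below −0.15 mm⁻¹ (mode `"mean"`). A trench whose full
  width is ~4–5 mm has floor H ≈ −0.2 mm⁻¹ while its walls sit near zero,
  so this selects fundus floors only. A Gaussian-curvature criterion
  (K > 0.05 mm⁻² with H < 0, mode `"gaussian"`) is available but cannot
  seed straight sulci, whose K vanishes along the fundus line; both
  criteria are exposed because the right choice is data-dependent.
* **Erosion.** Ordered homotopic thinning with an embedded watershed:
  boundary voxels are removed in increasing chamfer distance from the
  internal border (ties broken by mean curvature, then lexicographic index,
  for determinism), provided removal is a simple-point operation, the voxel
  is erodible by the curvature gate (union-boundary H below 1.0 mm⁻¹ by
  default — only extreme convexities resist), and the voxel is not hull,
  seed, or a watershed ridge (its removal would merge water carrying two
  distinct basin labels). Distance ordering makes the fronts from the two
  banks of a sulcus meet at the inter-bank midline, where voxels become
  non-simple and persist: the medial sheet. The curvature field is computed
  once on the initial union; an evolving-boundary recomputation was
  considered and rejected — the retained-sheet mechanism is the
  non-simplicity test, not the curvature, and a static field keeps the
  whole erosion deterministic and cheap. Voxels unreachable from the
  internal border are never removed, so thin sets with no WM adjacency are
  fixed points of the operator.
* **Classification and pruning.** Remaining voxels are classified by their
  topological numbers (C*: 26-components of the object in the
  26-neighbourhood; C̄: 6-components of the background in the
  18-neighbourhood touching the center) into interior, isolated, border,
  curve, curves, surface, surface-curve, surfaces and surfaces-curve.
  The implementation is validated against a brute-force flood-fill oracle
  over random 3×3×3 configurations, which is the source of truth for
  borderline cases. Pruning repeatedly deletes whole passes of deletable
  voxels until a fixed point. Surface-type classes are never deletable;
  the default deletable set is {isolated, curve, curves}, which removes the
  spurious branches of over-seeded basins in one pass per branch. Border
  voxels are *not* deleted by default: the free edges of a medial sheet are
  border-class, and deleting them unravels the sheet column by column.
  Users who want more aggressive pruning can add `"border"` explicitly.

Two structural caveats are inherent. Ordered thinning leaves 2-voxel-thick
blocks where three sheets meet (medial sheet, hull, side front); such
interior-class junction voxels are non-simple by definition and cannot be
removed by any topology-preserving pass — they are rare (fractions of a
percent of the skeleton) and harmless to the pial stage. And the medial
surface is a *hypothesis*: it is exactly right only where the two banks
have equal thickness, which is also the assumption the short-range
refinement is there to relax.

## Stage 3: Laplacian expansion and gradient refinement

A harmonic potential is solved on the union by Gauss–Seidel/SOR
(ω = 1.8, update residual < 10⁻⁵, cap 5,000 sweeps) with Dirichlet values 0
on WM and 1 on skeleton∪hull; domain walls act as Neumann boundaries. Both
the sulcal sheets and the hull carry the same value 1 — the streamline
simply stops at whichever it reaches first. Each WM vertex is advected
along the normalized gradient (RK2 midpoint, step 0.25 voxel) until the
potential reaches 1 − ε (ε = 0.02), a stop voxel is entered, or 30 mm of
arc length is exceeded (such vertices are flagged and assigned the nearest
stop voxel). Stop voxels are the skeleton *plus visibly segmented CSF*:
where CSF is observed the pial boundary is evidence, not hypothesis, and
stopping there keeps the intermediate surface from overshooting through
extracerebral CSF to the hull. Arrival points are then backed off 0.3 mm
toward their WM vertex so that opposing banks land on their own side of the
medial sheet, and a self-proximity pass separates parts closer than 0.1 mm.
Because every pial vertex is the endpoint of one streamline from one WM
vertex, the WM↔pial correspondence is one-to-one and crossing-free by
construction.

The refinement then fits the intensity edge. At each vertex a 1D profile is
sampled along the area-weighted normal by trilinear interpolation (step and
range per schedule level; out-of-volume samples are invalid), blurred with
a 1-sample Gaussian to remove micro-extrema, and searched for the maximum
signed gradient matching the expected polarity (`+1` rising outward, `-1`
falling, `"auto"` takes the largest magnitude — the same code fits both the
neonatal inverted contrast and adult-like contrast). The edge offset is
refined to sub-sample precision by parabolic interpolation. A profile whose
best gradient does not exceed twice a robust noise floor keeps its vertex
still; the floor is estimated from second differences of the profile
(zero on smooth ramps, σ√6 on white noise) rather than from the gradient's
own MAD, which would misread a broad edge as noise.

Each vertex's expected edge intensity may vary across the surface. By
default the target-intensity map is detected (intensity at the strongest
gradient, diffusion-blurred over the mesh with the symmetric uniform-weight
graph Laplacian, λ = 0.5, which conserves the total exactly); candidate
gradients are re-scored by a Gaussian similarity to the target. When a
segmentation is available the pipeline instead prescribes the target as the
midpoint of the *pure-tissue* means — per-label means over eroded label
masks, because partial-volume voxels drag naive means toward the
neighbouring tissue — with bandwidth |GM−CSF|/4. This matters when the GM
and CSF layers are only a couple of voxels thick: their two edges blur into
a single ramp whose gradient maximum is not the anatomical boundary, while
the half-way intensity still is. For the pial fit, candidate edges are
additionally restricted to the GM/CSF interface zone (GM voxels plus the
CSF layer touching GM), which excludes the unrelated CSF/background edge,
and displacement is clipped at the skeleton barrier so banks cannot cross
the medial sheet.

Deformation runs a coarse-to-fine schedule (WM fit: ±5/1, ±3/0.5,
±1.5/0.25 mm; pial fit: ±1.5/0.25 then ±0.75/0.125 mm — deliberately short
so the hypothesis-driven intermediate surface is only locally corrected),
moving each vertex at most `step_size` = 0.2 mm per iteration under
Laplacian regularization of the displacement field (weight 0.5),
terminating when the mean displacement falls below 0.02 mm, with a
divergence guard (abort after three consecutive >5% growths of the mean
displacement). Attraction and smoothness weights (1.0 / 0.5) are exposed;
they trade edge fidelity against mesh regularity, and the defaults were
chosen on noiseless shell phantoms as the weakest smoothing that keeps the
fitted sphere's radial scatter comparable to the sampling step.

## Stage 4: morphometry

*Thickness.* The default `linked` definition is the Euclidean distance
between corresponding WM and pial vertices — the correspondence exists by
construction and is the definition consistent with streamline expansion.
`nearest` (exact point-to-triangle) and `symmetric` are provided; nearest
is never larger than linked.

*Smoothing.* Per-vertex maps are smoothed by iterated symmetric graph
diffusion, with the iteration count calibrated so that a point impulse
attains a requested Gaussian FWHM: n = 3·(FWHM/2.355)²/(λ·h̄²) for mean
squared edge length h̄² (the factor 3 is an empirical calibration of the
discrete kernel against measured impulse spread on icosahedral meshes).
The default FWHM is 10 mm. The mean is conserved exactly and the variance
never increases; requests below the mean edge length return the raw map
with a warning.

*Sulcal depth.* The default is the exact shortest distance to the brain
hull mesh — a depth proxy that is zero on crowns and approximately the fold
depth at fundi; a smoothed `"potential"` variant exists behind the same
interface. Depth maps feed *template selection*: Pearson correlation
against each template's depth map (vertex correspondence given by
icosahedral resampling), argmax wins, ties break toward the smaller index
(templates conventionally ordered old→young), zero-variance maps are
excluded. Correlation makes the choice invariant to affine rescaling of
the depth map.

*Landmarks.* Quality assessment uses exact point-to-triangle distances from
world-mm landmark files to a surface, summarized as mean ± sd.

## The phantoms: what they emulate, and what they do not

The generator produces three geometries with analytic truth. The *shell*
(WM ball r1, GM shell r1..r2, CSF jacket, default 2 mm) has constant
thickness r2−r1. The *folded slab* is a WM block whose top carries periodic
sulci with parallel banks, built from a capsule signed-distance rule: the
sulcal gap (CSF width between banks) and the sulcal depth are exact input
parameters rather than by-products of a sinusoidal offset, because the
invisible-CSF condition — *no* pure CSF voxel inside a sulcus — must be
constructible and verifiable exactly. The *folded sphere* modulates a
shell's inner radius sinusoidally with latitude and exercises the
closed-topology code paths; its "thickness" truth is a radial offset, not a
normal distance, so only topology and QA properties are asserted on it.

Labels are produced by majority vote over a supersampled grid (default
factor 4), which is what a segmenter effectively does under partial volume:
a slot narrower than half a voxel can never win the vote, so the
invisible-CSF condition holds for any grid alignment. Intensities assign
the tissue means on the fine grid, box-average down (creating
partial-volume mixtures exactly at boundaries) and add seeded Gaussian
noise. Two presets bracket the contrast regimes: `neonatal`
(CSF 45, GM 85, WM 55 — low inverted WM–GM contrast, CSF≈WM) and `adult`
(CSF 30, GM 70, WM 110). Default study conditions used by the tests and
the acceptance script: 1 mm isotropic voxels, 64³ (slab) or ~56³ (shell)
grids, icosahedron level 4, noise 0 or 4 a.u. (10% of the GM–CSF
contrast), sulcal gap 0.4 mm vs 10 mm fold depth and 16 mm fold period.

What passing on phantoms does *not* show: robustness to bias fields,
motion, segmentation errors beyond partial volume, anisotropic voxels, or
real gyral geometry (curved, branching sulci of varying depth). The
phantoms isolate the geometric claims — topology correction, medial-surface
placement, harmonic correspondence, sub-voxel edge fitting — which are
exactly the claims the acceptance checks quantify.

## Numerical choices and degenerate inputs

* All meshes live in world mm; voxel indices are 0-based at voxel centers;
  conversion goes only through the NIfTI affine (stored as sform; the qform
  quaternion cannot represent shear or anisotropic scale). Round trips are
  identity to 10⁻⁹.
* The Laplace check against the closed-form radial harmonic uses the mean
  absolute deviation over the domain interior one voxel away from both
  boundaries: the voxelwise maximum is dominated by the half-voxel
  jagged-boundary ambiguity of the *rasterization* at any resolution and
  does not measure the solver.
* Erosion priority ties and queue order are fully deterministic
  (distance, curvature, voxel index), and every stochastic step takes an
  explicit seed, so identical configuration plus seed reproduces surfaces
  bit for bit.
* Degenerate inputs are handled explicitly: empty masks and missing files
  error with the offending path; masks touching the volume border are
  padded; a shell thinner than a voxel warns; an all-boundary Laplace
  domain returns its boundary values; flat profiles keep their vertex; a
  fold amplitude at or above the wavelength (self-intersecting geometry)
  is rejected.

## Known limitations

Hemisphere separation is a geometric midplane split of the WM bounding box
with per-component assignment — a stand-in for anatomical (corpus-callosum
based) separation, adequate for phantoms and roughly midsagittally aligned
volumes only. The medial-surface hypothesis biases the pial surface toward
the sulcus midline wherever banks truly differ in thickness and no
intensity gradient is recoverable. Junction voxels can leave isolated
2-thick spots in the skeleton. MINC input and a depth-potential sulcal
depth are interface stubs by design (NIfTI and hull distance are the tested
paths). Runtime is dominated by the erosion and the refinement; the bundled
sizes complete in seconds to a couple of minutes per stage on one CPU.
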