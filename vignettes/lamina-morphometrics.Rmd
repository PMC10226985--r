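---
title: "Subnuclear lamina ratiometry and 3D morphometrics: models, conventions and design choices"
author: "laminmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subnuclear lamina ratiometry and 3D morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(laminmorph)
```

## What the package measures and why

In the preimplantation embryo, the first lineage decision separates inner
cells (future inner cell mass) from outer cells (future trophectoderm), and
this positional difference is accompanied by mechanical differences that
register at the nucleus. The nuclear lamina — the Lamin intermediate-filament
meshwork lining the inner nuclear membrane — redistributes between a bright
peripheral shell and a dimmer nucleoplasmic pool depending on mechanical
state. The package quantifies this as the **L:N ratio**: the mean
fluorescence intensity over the lamina shell divided by the mean over the
nucleoplasm,

$$\mathrm{L{:}N} \;=\; \frac{\langle I \rangle_{\text{lamina shell}}}{\langle I \rangle_{\text{nucleoplasm}}}.$$

Around this readout the package implements the full supporting analysis:
nucleus and cell segmentation of multi-channel 3D volumes, cortex and
cytoplasm compartment masks built by micrometre-unit morphology,
DNA-stain-standardized intensities and nuclear:cytoplasmic ratios,
cytoplasmic filament-meshwork density, 3D shape descriptors of cells and
nuclei, FRAP recovery fitting with immobile-fraction estimation, and a
normality-routed statistical report of inner-versus-outer contrasts.

No public imaging data accompany this methodology, so the package ships a
synthetic embryo **phantom generator** with exact ground truth; every stage
is validated against phantoms, closed-form geometry, or brute-force oracles.

## The phantom generator: what it emulates, and what it does not

`phantom_spec()` / `generate_embryo_phantom()` build a 1–32-cell embryo as a
**seeded power-diagram partition of a ball**: cells designated *inner* get
centers near the embryo center, the rest sit on an outer shell (quasi-uniform
Fibonacci directions plus seeded jitter), and every voxel inside the embryo
is assigned to the center minimizing $\lVert p - c_i\rVert^2 - r_i^2$. This
gives space-filling, convex, blastomere-like cells, and — critically — makes
enclosure of inner cells *watertight by construction*, so the inner/outer
ground truth is unambiguous. The outer shell sits at 0.62 of the embryo
radius, which places the inner/outer power bisector so inner cells receive
volumes comparable to outer cells, as in real embryos. If a requested inner
cell nevertheless touches the exterior after rasterization, or a nucleus
cannot fit, generation aborts with a packing-failure error naming the cell.

Per cell the generator synthesizes:

* a **nucleus**: a sphere at the cell centroid whose radius is
  `nucleus_radius_fraction` of the cell's equal-volume radius (capped so it
  stays inside the cell). Surface wrinkling is a real spherical-harmonic
  radial perturbation $r(\theta,\varphi) = R\,(1 + a\,W(\theta,\varphi))$
  with $W$ a seeded random combination of degree-`wrinkle_order` harmonics
  normalized to unit RMS over the sphere, so `wrinkle_amplitude` $a$ is the
  RMS relative radial excursion and the analytic surface is available to
  oracle tests;
* a **lamin channel** that is piecewise constant before noise: nucleoplasm at
  `nucleoplasm_intensity`, the radial band of depth `lamina_thickness`
  beneath the nuclear surface at `true_ln_ratio` times that — so the L:N
  measured on the truth masks equals the requested value to machine
  precision;
* a **DNA-stain channel** uniform over the nucleus;
* a **membrane channel**: a cortical band within 0.6 µm of each cell
  boundary (always including the one-voxel boundary layer so the shell stays
  closed even where the z step exceeds the band width);
* an **actin channel**: the cortical band plus a cytoplasmic meshwork
  texture (seeded binomial speckle smoothed at 0.5 µm), normalized so its
  mean over each cell's cytoplasm equals `cytoplasmic_mesh_density` exactly;
* optionally a **marker channel** with per-cell nuclear and cytoplasmic
  levels, for nuclear:cytoplasmic ratio tests.

Noise is scaled-Poisson shot noise (gain `noise_poisson_scale`) followed by
Gaussian read noise (`noise_gaussian_sd`), each independently switchable so
exact identities can be tested noiselessly. Defaults (Gaussian SD 5 and
Poisson gain 1 on structures of intensity 100–150) give a signal-to-noise
ratio around 10, typical of live confocal imaging.

Default geometry emulates an 8-cell mouse embryo: embryo radius 26 µm,
blastomere radius weights ~10 µm, nuclei slightly over half the cell's
effective radius, voxel spacing (z, y, x) = (0.7, 0.35, 0.35) µm. The
anisotropic z step is deliberate: it forces every downstream computation
through physical-unit code paths, and unit errors show up immediately as
direction-dependent biases. The reported acquisition hardware gives no voxel
sizes, so these are choices, not inferences.

The phantom deliberately does **not** emulate: the microscope point-spread
function (edges are crisp), spectral bleed-through, intensity attenuation
with depth, embryo development over time (one static volume; FRAP is the
only time series), or non-convex cell shapes. Passing tests therefore show
correctness of the measurement pipeline under a standard noise model — not
robustness to optical blur or segmentation of irregularly shaped cells.

FRAP traces are generated with known plateau $I_\infty$ (`i_inf`) and
recovery time $\tau$: the noiseless normalized recovery is
$y(t) = I_\infty\,(1 - e^{-t/\tau})$, and the raw trace wraps this in an
additive background and a multiplicative per-frame photofade applied to both
the ROI and the reference, so a correct normalization must undo both.

## Segmentation and compartment conventions

**Nuclei** are segmented by Gaussian smoothing (0.5 µm), Otsu thresholding,
connected components, a distance-transform watershed split of components
carrying several cores, and a size filter (25 µm³). On phantoms this
recovers nuclei with Jaccard overlap above 0.99.

**Cells** are a seeded watershed: the smoothed membrane channel is the
relief, nucleus labels are the seeds, and the territory is the embryo
foreground — the thresholded membrane mask after a 1.2 µm morphological
closing, hole filling, and selection of the largest component. The closing
matters: where the cortical shell is one coarse z-voxel thick, smoothing plus
thresholding can open sub-voxel gaps through which hole filling would leak,
truncating outer cells.

**Micrometre-unit morphology.** Erosion and dilation threshold the
anisotropic Euclidean distance transform (computed by a separable
lower-envelope algorithm with per-axis spacing), so a "1 µm band" is 1 µm
deep along every axis regardless of voxel shape. Two surface conventions
coexist, deliberately:

* `erode_um()` / `dilate_um()` (used for the cortex/cytoplasm masks) place
  the surface at foreground voxel centers. The cortex band is ~2 µm wide and
  several voxels thick, so the half-voxel ambiguity is a small relative
  error (the analytic sphere-shell oracle is met within 10%, stable under
  resolution doubling within 5%).
* `split_lamina_nucleoplasm()` uses a **subvoxel-refined** distance
  (`subvoxel_distance()`): the occupancy is linearly upsampled 2×,
  thresholded at 0.5 — placing the surface midway between foreground and
  background voxel centers — transformed on the fine grid, and sampled back
  at voxel centers. The lamina shell is only 1–3 voxels thick, and the plain
  voxel-center convention systematically contaminates the nucleoplasm with
  shell voxels (about −9% bias in recovered L:N at a true ratio of 3);
  the refinement removes this (shell-volume oracle error +1.9%).

**Cortex and cytoplasm** follow the min/max-filter construction: masks about
1 µm larger and smaller than the cell; cortex = larger minus smaller;
cytoplasm = smaller minus nucleus. Whether the original bands were geodesic
or Euclidean is not stated in the methodology this reimplements; Euclidean
is used. In `quantify_embryo()` the cortex is additionally clipped to the
cell's own territory so a neighbor's voxels are never counted, and
`cytoplasmic_mesh_density()` refuses masks that overlap the cortex or
nucleus rather than silently diluting the signal.

**Inner/outer classification** uses strict face adjacency (6-connectivity)
to the background label, with the volume border counting as background —
the most conservative, resolution-stable reading of "no part of the cell
surface touches the embryo exterior". It is verified against an independent
brute-force per-voxel scan.

## Geometry: estimators and their conventions

* **Surface point clouds** are centers of boundary voxels (foreground with a
  face-adjacent background neighbor), in physical µm.
* **Apical surface**: points strictly closer than `cutoff_um` to any other
  cell's point set are deleted; ties at exactly the cutoff are retained. The
  cutoff default is 1.0 µm — the source methodology names a cutoff but no
  value. An empty apical set is meaningful (an inner cell). In the pipeline
  the same rule is evaluated via one cropped distance transform per cell
  (`apical_surface_from_labels()`), which is exact for voxel-center point
  sets; the equivalence is property-tested.
* **Apical area**: a full 3D Delaunay tetrahedralization's free boundary is
  the convex hull of the points, which for an isolated curved cap would add
  the flat "lid" closing the cap (for a 10 µm sphere capped at depth 3 µm:
  +160 µm² on a true 188.5 µm² cap) — so the free-boundary reading cannot
  reproduce the spherical-cap area it is supposed to. The package instead
  projects the patch onto its best-fit plane, triangulates the projection
  (2D Delaunay, Bowyer–Watson), maps triangles back to 3D, prunes triangles
  with an edge over 4× the median edge (these bridge holes or disjoint
  patches), and sums 3D triangle areas. This is the 2.5D construction,
  promoted from fallback to the primary route; it meets the analytic cap
  oracle within 5%.
* **Total cell area and sphericity** use radial ray-cast meshing
  (`surface_mesh_from_mask()`): rays from the mask centroid along icosphere
  directions locate the 0.5 crossing of the trilinearly interpolated
  occupancy, giving a closed, manifold, consistently oriented mesh with
  subvoxel surface localization. This replaces marching cubes; it is valid
  for star-shaped objects, which all phantom cells (convex power cells) and
  nuclei (bounded-amplitude radial perturbations) are by construction. Mesh
  area converges to the analytic sphere area within 2%, and sphericity
  $\Psi = \pi^{1/3}(6V)^{2/3}/A$ (volume from voxel counts) matches the
  Thomsen closed form for a 10:5:5 ellipsoid within 3%. For strongly
  non-star-shaped objects this estimator would under-resolve concavities —
  a known limitation.
* **Oriented bounding box**: the z axis points from the embryo center of
  mass to the apical-surface center of mass (falling back to the cell's own
  center of mass when the apical set is empty; the fallback is recorded in
  an attribute). In-plane axes minimize the $L_x L_y$ footprint by a
  0.25° grid search with golden-section refinement — exhaustive search over
  the single free angle is cheap and deterministic. Aspect ratio is
  $(L_z - \max(L_x, L_y))/(L_z + \max(L_x, L_y))$ and flatness is
  $L_{z,\text{api}}/L_z$.
* **Ellipsoid fit**: algebraic least squares on the quadric form (smallest
  singular vector of the design matrix), with the point cloud pre-aligned to
  its principal axes so the fit is rotation-equivariant, and constrained
  post hoc to a real ellipsoid (non-ellipsoid quadrics are an error with
  diagnostics). "Minimum ellipsoid" is read as *least-squares*, not the
  minimum-volume enclosing ellipsoid: the MVEE of a wrinkled surface touches
  only the outermost bumps, biasing the deformation index directionally,
  whereas the LS fit treats inward and outward excursions symmetrically.
* **Nuclear deformation index**: the mean over surface points of the radial
  distance to the fitted ellipsoid — measured along the ray from the
  ellipsoid center through the point — normalized by the point's distance to
  the center. The radial (not orthogonal) distance follows from the
  normalization "by the distance from center to the point", which implies a
  radial construction. For $r = R(1 + a\cos k\theta)$ the index approaches
  $2a/\pi$ (the mean of $\lvert\cos\rvert$), which the tests verify against
  a brute-force oracle; the index is zero exactly on the fitted ellipsoid
  and strictly increasing in wrinkle amplitude over $a \in \{0, 0.05, 0.1,
  0.2\}$.
* **Local curvature**: discrete mean curvature from the cotangent Laplacian
  with mixed Voronoi vertex areas (the Meyer construction; plain barycentric
  thirds leave ~15% errors at the icosphere's valence-5 vertices, mixed
  areas are exact to ~10⁻⁵ on a sphere). The sign is positive for locally
  convex vertices; the summary reports the distribution (mean, SD,
  quartiles), with the SD serving as a deformation score. The estimator and
  summary are this package's choices — the source methodology names local
  curvature analysis without specifying either.

## FRAP model and fitting

`normalize_trace()` computes $r(t) = (\mathrm{roi} - \mathrm{bg}) /
(\mathrm{ref} - \mathrm{bg})$ — cancelling gain and shared photofade — then
rescales so the pre-bleach mean is 1 and the first post-bleach frame is 0.
"Immediately after photobleaching" is the annotated `bleach_index` frame
(auto-detected as the largest single-frame drop when unannotated), and the
bleach frame itself is included in the fit as the $y = 0$ anchor.

`fit_recovery()` fits the single exponential $y(t) = I_\infty(1 -
e^{-(t-t_0)/\tau})$ by **variable projection**: for fixed $\tau$ the
amplitude is linear and solved in closed form, and the profiled sum of
squares is minimized over $\tau$ on a log-spaced grid with golden-section
refinement. This is deterministic given the data — no starting values, no
random restarts — and cannot fail to converge; $\tau$ at the search bounds
and plateaus outside $[0, 1]$ are flagged, not errors. The immobile fraction
is $1 - I_\infty$ identically. A single exponential is the minimal model
consistent with "fitted with an exponential function"; no double-exponential
or reaction–diffusion model is attempted (out of scope).

Under the tested noise grid ($I_\infty \in \{0.2, 0.5, 0.8\}$, $\tau \in
\{5, 20\}$ s, normalized noise SD 0.03, 50 seeds each) the median absolute
plateau error stays below 0.03.

## Statistical reporting

`route_and_test()` reproduces a normality-gated routing rule: every group is
tested with the D'Agostino–Pearson omnibus $K^2$ (implemented in-package:
standardized skewness and kurtosis, $K^2 \sim \chi^2_2$; verified against an
independent reference implementation to 7 digits) at $\alpha = 0.05$ — the
gate level is assumed, not stated in the source. All groups normal routes to
the unpaired two-tailed t-test (2 groups) or one-way ANOVA with Dunnett's
post hoc against the first group (more); otherwise the two-tailed
Mann–Whitney U (2 groups) or Kruskal–Wallis with Dunn's post hoc
(Bonferroni-adjusted within the family). Groups with $n < 8$ — too small for
the kurtosis approximation — route directly to the non-parametric branch and
are flagged. No multiplicity correction is applied across metrics, matching
the source convention of correcting only within multi-group post hocs.

The Mann–Whitney implementation uses mid-ranks for ties and enumerates the
exact null distribution of $U$ over all group assignments when
$\binom{n_1+n_2}{n_1} \le 40{,}000$ (valid with ties); larger samples use
the normal approximation with tie-corrected variance and continuity
correction. Exactness is tested against full enumeration for all
$n_1, n_2 \le 6$ and against `wilcox.test` where ties are absent.

`summarize_groups()` reports n, median, IQR, mean and SD per group; the
quartile convention is linear interpolation (R type 7), pinned so
$\{1,2,3,4\}$ gives median 2.5 and IQR 1.5.

## Problem sizes used by the tests and acceptance script

All validation runs on synthetic data sized for a single CPU: L:N parameter
recovery uses 4-cell phantoms (embryo radius 20 µm, nuclei ≈ 7 µm — chosen
so nuclei have realistic radii at cleavage stages) over true ratios
$\{1.0, 1.5, 2.0, 3.0\}$ with 10 seeds each at default noise;
inner/outer classification uses twenty 8–16-cell phantoms miniaturized onto
≤ 64³ grids (voxel spacing (1.0, 0.5, 0.5) µm, at most one designated inner
cell — at this scale a second center-adjacent cell leaves no room for a
well-formed nucleus) and is compared voxel-for-voxel with a brute-force
adjacency scan; the end-to-end demonstration is one 16-cell embryo (radius
28 µm) with three inner cells at true L:N 1.2 versus 2.0 outside, processed
by the full segmentation path. With these sizes the whole suite and the
acceptance script each run in minutes.

## Known limitations

* No PSF or depth attenuation in the phantom: segmentation accuracy on real
  confocal stacks with optical blur is untested here.
* Radial meshing assumes star-shaped objects; deeply lobed or folded cells
  would need a general isosurface extractor.
* The projected-Delaunay apical area assumes the apical patch is a graph
  over its best-fit plane; patches wrapping far beyond a hemisphere would
  fold in projection (pruning mitigates, but does not eliminate, the
  resulting error).
* The lamina shell thickness for the L:N split (1 µm) is a documented,
  configurable choice; the source methodology does not state the value used.
* FRAP fitting is phenomenological: $\tau$ is a recovery timescale, not a
  diffusion coefficient.
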