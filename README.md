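# laminmorph

Quantification of nuclear-lamina mechanoresponse and 3D cell/nucleus shape
in preimplantation embryos, from multi-channel confocal volumes.

During the first lineage segregation of the mammalian embryo, inner cells
(future inner cell mass) and outer cells (future trophectoderm) experience
different mechanical environments, and the nuclear lamina registers this:
Lamin redistributes between the bright shell lining the nuclear envelope and
the dimmer nucleoplasmic pool. The package's central readout is the
**lamina:nucleoplasm (L:N) intensity ratio**

    L:N = mean(I, lamina shell) / mean(I, nucleoplasm)

together with everything needed to compute and interpret it at scale:

* **Segmentation** — nuclei from a DNA stain (smoothing + Otsu + watershed
  split), cells by seeded watershed on a membrane/cortex channel, and
  subnuclear compartments: the nucleoplasm is a physical-unit (1 µm,
  subvoxel-refined) erosion of the nucleus, the lamina shell its complement;
  cortex and cytoplasm come from masks ±1 µm around the cell.
* **Intensity statistics** — DNA-stain-standardized compartment intensities,
  nuclear:cytoplasmic ratios, cytoplasmic F-actin meshwork density.
* **Geometric morphometrics** — apical (contact-free) surface extraction and
  area; radially oriented minimal bounding boxes with aspect ratio
  `(Lz − max(Lx, Ly)) / (Lz + max(Lx, Ly))` and flatness `Lz_api / Lz`;
  distance to the embryo center of mass; least-squares ellipsoid fits and
  the nuclear deformation index (mean normalized radial distance to the
  fitted ellipsoid); sphericity `π^(1/3) (6V)^(2/3) / A`; discrete mean
  curvature.
* **FRAP** — trace normalization (background, reference photofade, pre-bleach
  = 1, first post-bleach frame = 0) and deterministic single-exponential
  fitting `y(t) = I∞ (1 − e^(−t/τ))`, with the immobile fraction `1 − I∞`.
* **Statistics** — the normality-routed reporting rule
  (D'Agostino–Pearson gate at α = 0.05; t-test / ANOVA + Dunnett when
  normal, Mann–Whitney U / Kruskal–Wallis + Dunn otherwise, all two-tailed),
  with exact small-sample Mann–Whitney enumeration, and group summary
  tables (n, median, IQR, mean, SD).
* **Synthetic embryo phantoms** — because no public imaging accompanies this
  methodology, a first-class generator builds 1–32-cell embryos with exact
  ground truth (known per-cell L:N, inner/outer status, wrinkle amplitude,
  meshwork density) and Poisson–Gaussian noise, so every stage is testable
  end to end. See the vignette (`vignettes/lamina-morphometrics.Rmd`) for
  the generator's model and every numerical convention.

The intended users are quantitative embryologists and mechanobiology labs
who need a scriptable, fully specified reimplementation of this measurement
stack — each step otherwise lives in interactive commercial tools.

## Worked example

`analysis/` contains the numbered workflow. Step 1 simulates a 16-cell
embryo (radius 28 µm, voxels 0.7×0.35×0.35 µm) whose three inner cells get
true L:N 1.2 (outer: 2.0) and a doubled cytoplasmic meshwork density;
steps 2–5 segment it, quantify it, and run the statistics:

```sh
Rscript analysis/01_simulate_phantom.R
Rscript analysis/02_segment_compartments.R
Rscript analysis/03_quantify_records.R
Rscript analysis/04_frap_analysis.R
Rscript analysis/05_group_statistics.R
```

prints, in order:

```
phantom: 16 cells (3 inner), grid 88x175x175 voxels at 0.7x0.35x0.35 um, true L:N inner 1.20 / outer 2.00
segmented 16 nuclei, 16 cells; inner/outer agreement with truth: 100%
quantified 16 cells: median L:N inner 1.158 / outer 1.869 (true 1.2 / 2.0)
mean |L:N error| vs truth: 5.9%
FRAP: median immobile fraction inner 0.562 (true 0.55) vs outer 0.296 (true 0.30); t p = 5.49e-17
ln_ratio               mann_whitney   p = 0.003571
mesh_density           mann_whitney   p = 0.003571
distance_to_embryo_cm  mann_whitney   p = 0.003571
apical_fraction        mann_whitney   p = 0.003571
```

Reading the numbers: the pipeline recovers the constructed inner < outer
L:N contrast (1.158 vs 1.869, within ~6% of the truth; the residual bias
comes from boundary voxels of the 1 µm shell), classifies every cell's
inner/outer position correctly, finds the denser inner-cell meshwork
(medians 0.805 vs 0.405 in DNA-stain-standardized units, a 2.0× contrast as
constructed), and the routed Mann–Whitney test (both groups are below the
n = 8 normality-test minimum, so routing is non-parametric and flagged)
rejects at p = 0.0036 — the exact two-tailed minimum for 3 vs 13 perfectly
separated observations. Inner cells have apical fraction 0: no contact-free
surface, the defining property of an internalized cell. The FRAP step fits
simulated inner/outer recovery curves and recovers the immobile fractions
to within 0.02.

Outputs land under `results/` (volumes and label maps as TIFF + JSON
sidecar, per-cell records as CSV, reports as JSON).

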