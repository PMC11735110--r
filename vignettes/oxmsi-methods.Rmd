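---
title: "oxmsi: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{oxmsi: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxmsi)
```

This vignette is the package's own account of the science it implements:
the models, the assumptions behind them, the tunable parameters and their
defaults, what the synthetic phantoms do and do not emulate, and the
numerical choices made where the design was genuinely open.

## 1. Exact-mass lipid chemistry

Oxygenated phosphatidylethanolamines (oxPE) are annotated at the
sum-composition level: `PE(C:db)+kO` is a diacyl PE with `C` total acyl
carbons, `db` total double bonds and `k` added oxygen atoms. The molecular
formula of the neutral species follows from the
glycerophosphoethanolamine backbone plus two acyl chains:

$$\mathrm{C}_{C+5}\,\mathrm{H}_{2C-2db+10}\,\mathrm{N}\,\mathrm{O}_{8+k}\,\mathrm{P}$$

and the deprotonated ion observed in negative mode is

$$m/z\,[\mathrm{M-H}]^- = M_\text{mono} - m_\mathrm{H} + m_e .$$

Atomic masses are CODATA/IUPAC monoisotopic values hard-coded to at least
six decimals; the electron mass (0.00055 Da) is below every printed
precision in this workflow but is included for exactness. Only diacyl PE
is modeled — plasmalogen and ether PEs are out of scope, as are isotope
envelopes and MS/MS fragments. Oxygen additivity is exact by construction:
adding `k` oxygens shifts the ion by exactly `k` × 15.994915 Da, which the
tests sweep across C ∈ [34, 44], db ∈ [2, 6], k ∈ {1, 2, 3}.

Peak annotation mirrors standard high-resolution LC-MS practice: peaks
with signal-to-noise **strictly** greater than 3 are retained, then each
peak is matched to the database entry with the smallest |ppm error| within
a tolerance (default 5 ppm, appropriate for Orbitrap-class mass accuracy;
configurable). Two open choices are made explicit here:

* *Database coverage.* The in-house database coverage is not prescribed
  anywhere, so `build_oxpl_database()` defaults to PE, C ∈ [34, 44],
  db ∈ [2, 6], +1..3 O — wide enough to contain every species this
  workflow names — and everything is a parameter.
* *Tie-breaking.* If two entries are equidistant in ppm, the lower-m/z
  entry wins, making output deterministic.
* *Retention-time windows* are optional (no numeric windows are
  prescribed); when given, they veto mass matches outside the window.

## 2. Imaging data model

`msi_grid` stores per-pixel centroided spectra row-major on a rectangular
raster; `extract_channel` sums intensities in a **closed** m/z window
(default half-width ±0.05 Da — vendor software does not expose the value
it uses, so this is an explicit, configurable choice). Coordinates are
0-based `(row, col)` with pixel centers on integers; closed windows and
explicit pixel-center conventions make edge behavior deterministic.

Two containers are supported: a plain-text internal format (JSON metadata
plus a long-form CSV of peaks — chosen over an HDF5-style store so that
datasets remain diffable, portable text) and read-only imzML import
(continuous and processed binary modes, 32- and 64-bit floats), parsed
directly from the XML and external binary arrays.

Operations that would silently mix modalities (e.g. a ratio of a lipid to
a protein channel) refuse to run unless the shapes *and* modalities agree;
lipid channels enter protein image space only through `resample_channels`.

## 3. Cross-sample normalization

Two samples acquired in separate runs differ by a global sensitivity
factor. A reference lipid assumed biologically invariant between
conditions — cholesterol sulfate, [M−H]⁻ at m/z 465.30 — is imaged in
both. Its mean signal is measured in `k = 13` randomly placed 15 × 15 px
regions of the tissue per sample, and the correction factor is the ratio
of the two means; multiplying sample B by it reproduces sample A's scale.

Open choices, made deliberately:

* **Ratio of means, not mean of ratios** (default): robust to individual
  near-zero regions; the paired estimator is available via
  `method = "mean_of_ratios"`.
* **Independent region draws per sample.** The regions need not be
  matched anatomical locations — the two samples are different sections —
  so each sample draws its own regions from its own tissue mask.
* **Tissue mask = Otsu foreground of the smoothed reference channel.**
  The mask must (a) exclude bare substrate, (b) exclude the dim tissue
  boundary, where region means are dominated by partial tissue coverage
  rather than sensitivity, and (c) not contain shot-noise holes, since a
  region footprint must lie wholly inside it. Thresholding a
  Gaussian-smoothed (σ = 2 px) copy of the reference image at its Otsu
  threshold satisfies all three; a global-quantile mask
  (`tissue_mask = "quantile"`) is kept as an alternative but fails (b) on
  images that are mostly background.

The ratiometric oxPE/PE image follows the grayscale rendering convention:
pixelwise `5 × ox / precursor`, precursor-zero pixels masked (or zeroed on
request). The ×5 scaling and the 12-bit depth are treated as display
parameters only — `quantize_channel()` applies them at export, while all
statistics run on unquantized floating-point ratios.

## 4. Affine coregistration

The lipid (moving) image is registered onto the protein (fixed) image by
minimizing the mean squared intensity difference. Conventions and
numerics, all of which the original tooling hides:

* **Pull-back transform.** The estimated transform maps fixed-image pixel
  coordinates to moving-image coordinates, which is exactly what
  resampling needs: every lipid channel is interpolated at `T(x)` for each
  fixed pixel `x`. Serialization records the convention explicitly.
* **Objective.** Both images are min-max normalized to [0, 1]. The MSE is
  averaged over fixed pixels whose pull-back lands inside the moving
  image; if fewer than 25 % do, a maximal surrogate value is returned so
  the optimizer treats the configuration as unacceptable, and a start
  with no usable overlap raises an error advising manual pre-alignment.
* **Optimizer.** All six affine parameters are optimized jointly, in a
  centered parameterization (rotation/scale about the image center) that
  decouples them from translation. Steps follow the analytic gradient
  (chain rule through bilinear interpolation of precomputed central
  difference images), scaled by the diagonal of the Gauss–Newton
  approximation (Jacobi preconditioning) — without this, translation and
  linear parameters differ in curvature by the squared image radius and
  plain gradient descent stalls. A backtracking line search accepts a
  step only if the objective decreases, so the trace of accepted values
  is non-increasing by construction. Convergence is declared when the
  relative decrease falls below `tol` (default 1e-9).
* **Initialization and pyramid.** The translation starts at the offset of
  the intensity centers of mass; the linear part at identity. A
  coarse-to-fine pyramid (block-mean ×2 per level, default 3 levels,
  finest level full resolution) extends the capture range. The method is
  fully deterministic.
* **Pixel-size mismatch.** If the modalities were sampled at different
  pixel sizes, the moving image is first resampled onto the fixed grid
  spacing in physical micrometers, and the scaling is folded back into
  the returned transform.
* **Channel choice.** Which channels have "representative morphology" is
  a data-dependent choice the user makes; the pipeline defaults to the
  panCK composite (fixed) and the parent PE channel (moving), which carry
  the same cell-body geometry in the phantoms.

Accuracy is summarized as mean corner displacement: the mean distance
between the four image corners mapped through the estimated and the true
transform. The test suite requires < 1 px on 256 × 256 phantoms over 20
random truths (|shift| ≤ 10 px, |rotation| ≤ 10°, scale 0.95–1.05) and
composition consistency (A→B ∘ B→C ≈ A→C) within the same bound.

## 5. Segmentation and per-cell quantification

Pretrained deep-learning segmenters are the current standard for imaging
cytometry, but shipping trained network weights is out of scope here, and
the scientific content downstream — integration, typing, statistics —
does not depend on the segmenter's identity. The default is therefore a classical,
deterministic seeded watershed: Gaussian smoothing (σ = 2 px), Otsu
threshold of the nuclear channel, distance-transform watershed to split
touching nuclei into seeds, then Voronoi propagation of the seeds over a
cell mask weighted by the membrane channel, so boundaries settle on
membrane ridges. Labels are filtered by area (default ≥ 20 px) and
renumbered in raster order of their centroids. The segmentation stage sits
behind the `label_map` interface, so an externally produced label image
can be imported instead. A blank nuclear channel yields an empty
segmentation with a warning rather than an error.

Per-cell integration is an exact partition: each channel is summed over
each cell's pixels, so totals over cells equal totals over labeled pixels
to the last bit — asserted, not just hoped, in the tests.

Cell typing applies threshold rules in precedence order to integrated
(area-normalized by default) marker signals. Thresholds may be manual or
automatic, and the right automatic rule depends on the marker's
distribution: Otsu for genuinely bimodal markers (K14: positive basal
cells vs negative), half-the-population-median for markers expressed by
essentially all cells (panCK), where a bimodal split would bisect a
unimodal population. Cells matching no rule are `"unassigned"`.

Group statistics use the Welch (unequal-variance) two-sided t test — the
safer choice when only "Student's t test" is prescribed — on per-cell
integrated counts (raw by default; area-normalized on request, since
whether per-cell "signal intensities" are sums or means is not
prescribed). Hierarchical clustering defaults to Ward linkage on Euclidean
distances over z-scored variables — none of the three is prescribed, so
all are parameters.

## 6. PLS-DA and VIP

The discriminant analysis is implemented as two-class PLS-DA fitted by
NIPALS on the autoscaled variable matrix against a centered 0/1 response,
with the standard VIP score

$$\mathrm{VIP}_j = \sqrt{p \cdot \frac{\sum_a \mathrm{SSY}_a\,(w_{ja}/\lVert w_a\rVert)^2}{\sum_a \mathrm{SSY}_a}},$$

where $\mathrm{SSY}_a$ is the response variance explained by component
$a$. The normalization identity mean(VIP²) = 1 holds to machine precision
for any input and is tested as such. An orthogonalized variant (OPLS-DA)
differs only in how variance is shuffled between components for two-class
problems; VIP magnitudes and rankings are comparable, and plain PLS-DA is
fully specifiable without vendor software. Two components are the default
(the number used in the vendor tool is not prescribed). The test suite
cross-checks the scores against an independent PLS-DA implementation
(mixOmics) to 1e-6 and requires the designed discriminating variable to
rank first in ≥ 19 of 20 seeded simulations.

## 7. The phantom: what it emulates, and what it does not

`generate_phantom()` renders one synthetic tissue section in both
modalities with complete ground truth:

* **Geometry.** Non-overlapping disks (radius 4–7 px) with soft sigmoid
  edges, placed by rejection sampling inside a circular tissue plateau
  (radius 0.42 × image size). The default of 100 cells on a 256 × 256
  grid sits comfortably below the random-sequential-adsorption packing
  limit of that geometry (~125 cells), so placement succeeds for any
  seed. Nuclei are concentric smaller disks; membranes are annuli — the
  simplest geometry that exercises a seeded watershed.
* **Types and markers.** 30 % K14⁺ / 70 % panCK⁺K14⁻ by default; per-type
  mean channel intensities (K14 high only in K14⁺ cells, panCK in both).
* **Lipids.** Per-cell log-normal abundance multipliers (σ = 0.3) around
  per-species median densities; oxPE species are multiplied 3-fold in
  K14⁺ cells of the *lesional* condition only. Cholesterol sulfate is
  rendered type- and condition-independently across the tissue plateau —
  it is the normalization reference and must carry no biology.
* **Physics.** The lipid modality observes the same scene through a known
  affine misalignment (default: 2° rotation, 1.01 scale, (4, −3) px
  shift) — rendered analytically at warped coordinates, so no
  interpolation error enters the ground truth — and, in the lesional
  condition, through a 1/8.6 sensitivity factor. Poisson noise is applied
  last, on expected counts, per the counting-detector model.
* **Determinism.** All randomness flows from one seed through fixed
  sub-seeds per stage (geometry, types, abundances, per-channel noise),
  so each stage is independently reproducible and the same seed gives
  bit-identical output.

What the phantom does **not** emulate: real spectra (isotope envelopes,
matrix peaks, peak shape), chromatographic structure, irregular cell
morphology, spatial correlation of cell types (basal layers), partial
occlusion between modalities, or detector saturation. Passing the
closed-loop tests therefore demonstrates that the *computational chain*
recovers known truth under its stated model — cells resolvable by nuclear
seeds, misalignment truly affine, reference lipid truly invariant,
counting noise — not that the chain is robust to every failure mode of
real tissue data.

## 8. Pipeline orchestration

`run_pipeline()` executes normalize → register → resample → segment →
integrate → classify → cluster/VIP → compare, writes every stage product
as CSV/JSON under the output directory, and emits a report whose every
number traces to one of those artifacts. Any stage failure halts the run
with the stage name; no partial report is written. Re-running the same
configuration and seed reproduces `report.json` bit-identically — the
report carries no timestamps, and provenance records the package version,
seed and an MD5 fingerprint of the configuration. Content-hash caching of
clean stages was considered and dropped: at desk scale every stage runs
in seconds, and the idempotence guarantee makes re-runs cheap and
auditable.

Problem sizes used by the shipped validation suite, chosen as desk-scale
study conditions: 256 × 256 phantoms with 100 cells for the end-to-end
and recovery checks (20 random transforms for registration; 200 smaller
cells for the segmentation count check), 176 × 176 with 60 cells for the
faster orchestration tests, n = 100 × 10 matrices over 20 seeds for VIP.

## 9. Known limitations

* Sum-composition annotation cannot distinguish isomeric oxPE species or
  sn-positional isomers; MS/MS confirmation is out of scope.
* MSE registration assumes the chosen channel pair looks similar after
  [0, 1] normalization; strongly multimodal contrast would need a mutual
  information metric, which is out of scope. Only 2D affine motion is
  modeled — no deformable registration.
* The watershed segmenter expects roughly convex cells with detectable
  nuclei; densely packed or flat cells will merge or fragment. The label
  map import path exists precisely for externally segmented data.
* The correction factor is a single global gain; spatially varying matrix
  effects are not modeled.
* PLS-DA VIP inherits the usual caveats of component-based importance:
  scores depend on the number of components and on autoscaling.
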