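# oxmsi

Single-cell spatial analysis of oxidized phospholipids from dual-modality
mass spectrometry imaging (MSI).

## The problem

Ferroptosis — iron-dependent cell death driven by peroxidation of
polyunsaturated phospholipids — leaves a chemical signature in tissue:
oxygenated phosphatidylethanolamine (oxPE) species such as PE(38:4)+2O and
PE(40:4)+2O, the di-oxygenated arachidonoyl-PE death signals. Bulk LC-MS
lipidomics detects these signals but cannot say *which cells* carry them.
Dual-beam secondary ion mass spectrometry imaging can: a water-cluster GCIB
beam images lipids at micrometer resolution, and a subsequent C60 beam
images lanthanide-tagged protein markers (nuclear, membrane,
pan-cytokeratin, keratin-14) on the same section. Turning those two image
stacks into per-cell lipid chemistry requires a chain of computational
steps, each of which this package implements and tests:

1. **Exact-mass annotation** (`ion_mz`, `build_oxpl_database`,
   `match_peaks`, `filter_snr`): combinatorial [M−H]⁻ oxPE databases from
   monoisotopic atomic masses; LC-MS peak tables filtered at S/N > 3 and
   matched by ppm error and retention time.
2. **Mass-channel imaging** (`read_msi`, `read_imzml`, `extract_channel`,
   `assemble_tiles`): per-pixel spectra to channel images, closed m/z
   windows, tiled acquisition.
3. **Cross-sample normalization** (`estimate_correction_factor`): samples
   acquired in different runs differ by a global sensitivity factor;
   a reference lipid assumed invariant between conditions (cholesterol
   sulfate, m/z 465.30) is measured in k random tissue regions per sample
   and the ratio of means rescales one sample onto the other.
4. **Affine coregistration** (`register_affine`, `resample_channels`): the
   lipid (moving) image is registered onto the protein (fixed) image by
   minimizing the mean squared intensity difference with a line-searched,
   preconditioned gradient descent over the six affine parameters, coarse
   to fine; all lipid channels are then resampled into protein image space.
5. **Single-cell quantification** (`segment_cells`, `integrate_cells`,
   `classify_cells`): seeded-watershed segmentation from nuclear + membrane
   channels, exact per-cell integration of every channel, marker-threshold
   typing (K14⁺ vs panCK⁺K14⁻).
6. **Statistics** (`cluster_cells`, `compare_celltypes`, `plsda_vip`):
   hierarchical clustering of z-scored lipid profiles, Welch two-sided
   t tests between cell types, and PLS-DA variable importance in projection
   (VIP; `VIP_j = sqrt(p * Σ_a SSY_a (w_ja/||w_a||)² / Σ_a SSY_a)`, so
   `mean(VIP²) = 1`).
7. **Ground-truth phantoms** (`generate_phantom`, `generate_phantom_pair`,
   `generate_peak_table`): synthetic dual-modality tissue sections with
   known cells, types, abundances, misalignment and sensitivity factor, so
   the whole chain is validated closed-loop.

`run_pipeline()` composes steps 3–6 end to end and writes per-stage
artifacts plus a machine-readable report.

## Worked example

```r
library(oxmsi)

sp <- lipid_species("PE", 40, 4, added_oxygens = 2)
species_formula(sp)   # C45H82NO10P
ion_mz(sp)            # 826.5604

rep <- run_pipeline(pipeline_config(seed = 11, out_dir = "run"))
print(rep)
```

```
oxmsi pipeline report
  correction factor: 8.444
  control: registration MSE 0.0125 (22 iters); cells: K14+=28, panCK+K14-=72
  lesional: registration MSE 0.026 (19 iters); cells: K14+=34, panCK+K14-=66
  top VIP species:
    PE(38:4)+2O      VIP = 1.293
    PE(40:4)+2O      VIP = 1.060
    PE(40:4)         VIP = 0.452
  cell-type comparisons (per condition, Welch two-sided):
    control   PE(40:4)       K14+/panCK+K14- fold 1.07, p = 0.304
    control   PE(40:4)+2O    K14+/panCK+K14- fold 1.04, p = 0.64
    control   PE(38:4)+2O    K14+/panCK+K14- fold 1.06, p = 0.602
    lesional  PE(40:4)       K14+/panCK+K14- fold 0.97, p = 0.801
    lesional  PE(40:4)+2O    K14+/panCK+K14- fold 3.01, p = 5.77e-10
    lesional  PE(38:4)+2O    K14+/panCK+K14- fold 3.07, p = 3.4e-12
```

Reading the report: the simulated lesional section was generated with a
lipid-modality sensitivity of 1/8.6 — the estimated correction factor
(8.44) recovers it. Each section's lipid stack was registered onto its
protein stack (final mean squared difference and accepted iterations
shown), cells were segmented and typed, and the designed biology appears
exactly where it should: the oxPE species are ~3-fold higher in K14⁺ cells
of the lesional section only (Welch p < 1e-9), the parent PE(40:4) is not,
and the two oxPE species top the VIP ranking that discriminates the
conditions. Per-stage numbers are in `run/` (`correction_factor.json`,
`transform_*.json`, `cells_*.csv`, `vip.csv`, `comparisons.csv`,
`report.json`).

A thin CLI wraps the same functions: `inst/exec/oxmsi run --config
config.yaml`, `oxmsi simulate`, `oxmsi register`, `oxmsi mz`.

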