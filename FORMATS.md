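# File formats

All files are plain text. Matrices are tab-separated; tables are CSV;
metadata and reports are JSON.

## Cohort directory (written by `write_cohort` / `cmd_simulate`)

| file | contents |
|---|---|
| `modality_<NAME>.tsv` | subjects × features matrix; first column `subject_id`, header row of feature ids. One file per modality (e.g. `modality_FC.tsv`, `modality_FA.tsv`, `modality_GMV.tsv`). |
| `phenotype.csv` | `subject_id, group, age, sex, meanFD, onset_age, MMSE, HSCT`. `group` is `control`/`patient`; `sex` is 0/1; `meanFD` in mm; clinical columns may contain `NA`. |
| `reference.csv` | `subject_id, beta` — the per-subject reference (methylation β-value in [0,1]). Missing subjects are dropped from fusion. |
| `ground_truth.json` | simulation only: target component index, latent vector, generator configuration. |
| `truth_sources_<NAME>.tsv`, `truth_loadings_<NAME>.tsv` | simulation only: planted sources (components × features) and loadings (subjects × components), headerless. |
| `manifest.json` | command, seed, package version, configuration snapshot. |

`read_cohort()` reloads a directory in this layout; modality files are
read in alphabetical order and aligned to the `phenotype.csv` subject
order.

## Results directory (written by `write_fusion_result` / `cmd_fuse`)

| file | contents |
|---|---|
| `loadings_<NAME>.tsv` | subjects × components loading matrix, headerless. |
| `maps_<NAME>.tsv` | components × features joint map matrix, headerless, rows unit SD, sign aligned control > patient. |
| `statistics.csv` | `component, modality, t, p, q, r_ref, p_ref, q_ref, r_partial, selected` (q-values BH-corrected over the components × modalities family). |
| `clinical_correlations.csv` | `modality, score, n, r, p, component` for selected joint components (pairwise-complete observations). |
| `manifest.json` | configuration, seed, convergence flags, achieved objective, input file checksums, elapsed time. |

## Replication report (written by `cmd_replicate`)

| file | contents |
|---|---|
| `similarity_<NAME>.csv` | runs × runs matrix of pairwise absolute spatial correlations between each run's selected component map. |
| `overlap_<NAME>.tsv` | 0/1 vector: features surviving the \|Z\| threshold in at least two runs. |
| `report.json` | run labels, representative component per run × modality, similarity matrices, subset membership, seed. |

## Configuration file (`cmd_simulate --config`)

Flat YAML mirroring `simulation_config()` fields, all optional:

```yaml
n_patients: 60
n_controls: 60
features_per_modality: [300, 300, 300]
n_sources: 5
rho_ref: -0.4
group_effect_d: 0.8
clinical_effects: {onset_age: 0.6, MMSE: 0.35, HSCT: 0.3}
noise_sd: 0.5
seed: 42
```

## NIfTI (optional, requires RNifti)

`read_nifti_features(files, mask_file, modality)` builds a voxel feature
matrix from one volume per subject; the binary mask defines feature
order (ascending linear index, x-fastest). `export_nifti_map(map, mask,
file)` writes a feature-space map back into the masked volume.
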