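# refusion

Reference-guided fusion of multimodal neuroimaging data: multi-set
canonical correlation analysis with a reference signal (MCCAR) plus joint
independent component analysis, in R.

## The problem

Imaging-epigenetics studies ask how a molecular measurement — here the DNA
methylation level (β-value) at a CpG site — relates to covarying patterns
across several MRI modalities at once: functional connectivity (FC) edge
strengths, fractional anisotropy (FA) voxel values, and gray matter volume
(GMV) voxel values, each stored as a subjects × features matrix. A purely
unsupervised fusion finds components that covary across modalities but has
no reason to align any of them with the molecular measure. `refusion`
implements the supervised alternative: the decomposition is steered so
that some components also correlate with the reference, and the package
then runs the full downstream workflow — component selection by FDR, group
statistics, clinical and partial correlations, locus-wise differential
methylation, and subset-replication stability — on top of it.

Because studies of this kind rarely deposit raw data, the package ships a
synthetic-cohort generator with planted ground truth (shared latent,
sparse sources, group effect, reference and clinical correlations), so
every stage of the pipeline is testable end to end and parameter-recovery
claims are checkable rather than asserted.

## The model

Each modality *k* is whitened to `Y_k` and given an orthonormal weight
matrix `W_k`; the canonical variates are `D_k = Y_k W_k`. The weights
maximize

    J = Σ_{i<j} Σ_c corr(D_i[,c], D_j[,c])²  +  λ Σ_k Σ_c corr(D_k[,c], ref)²

— inter-modality covariation plus a reference-correlation term weighted by
λ (0.5 is the usual cross-validated choice; `refusion` can re-select it by
subject-wise cross-validation). The canonical maps are then concatenated
across modalities and rotated to independence by joint ICA
(natural-gradient infomax by default), subject loadings are recomputed
against the final joint maps, component signs are aligned so control >
patient, and every (component, modality) pair is tested for a group
difference and a reference correlation with Benjamini–Hochberg correction
over the components × modalities family. A component that survives both
tests in a modality is *selected*; one selected in every modality is the
joint component of interest.

## Worked example

```r
library(refusion)

cfg <- simulation_config(n_patients = 60, n_controls = 60,
                         features_per_modality = c(300, 300, 300),
                         rho_ref = -0.4, group_effect_d = 0.8, seed = 42)
cohort <- generate_multimodal(cfg)
result <- fuse_cohort(cohort, n_components = "auto", lambda = 0.5, seed = 42)
result
#> <fusion_result> 120 subjects, 3 modalities, M = 5, lambda = 0.5
#>   converged: TRUE | joint component(s) selected: 1

subset(result$statistics, selected)
#>    component modality    t        p        q  r_ref    p_ref    q_ref r_partial selected
#> 1          1       FC 4.40 2.44e-05 1.27e-04 -0.523 9.09e-10 9.93e-09    -0.513     TRUE
#> 6          1       FA 4.79 5.12e-06 7.67e-05 -0.508 3.07e-09 1.53e-08    -0.499     TRUE
#> 11         1      GMV 4.39 2.54e-05 1.27e-04 -0.518 1.32e-09 9.93e-09    -0.508     TRUE
```

The generator planted a single joint component whose loadings are shifted
down in patients (`group_effect_d = 0.8`) and correlate negatively with
the methylation reference (`rho_ref = -0.4`). The pipeline chose the model
order by MDL (M = 5, the true source count), selected exactly that
component in all three modalities (two-sample t ≈ 4.4–4.8, all q < 0.001),
and estimated reference correlations of −0.51 to −0.52 that shrink only
slightly (−0.50 to −0.51) after partialling out the group effect — the
planted structure, recovered. The spatial maps match the planted sources:

```r
jc <- result$joint_selected
sapply(seq_along(result$maps), function(k)
  spatial_similarity(result$maps[[k]][jc, ],
                     cohort$truth$sources[[k]][cfg$target_component, ])$abs_r)
#> 0.984 0.993 0.998
```

and the clinical correlations come out at their planted levels (age of
onset r ≈ 0.7 in patients, MMSE r ≈ 0.26, HSCT r ≈ 0.2):

```r
result$clinical
#>   modality     score   n    r       p component
#> 1       FC onset_age  60 0.72 1.1e-10         1
#> 2       FC      MMSE 120 0.26 3.7e-03         1
#> ...
```

Replication stability and the command line:

```r
rep <- run_subset_replication(cohort, "two_thirds", n_repeats = 2,
                              seed = 42, n_components = 5, lambda = 0.5)
rep$similarity$GMV     # pairwise |r| between selected maps across reruns
```

```sh
inst/cli/refusion simulate --config cfg.yaml --seed 1 --out cohort/
inst/cli/refusion fuse --cohort cohort/ --out results/ --lambda 0.5
inst/cli/refusion replicate --cohort cohort/ --out report/ --n-repeats 2
```

File formats for all of the above are described in `FORMATS.md`.

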