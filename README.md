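# ivafuse

Joint blind source separation of multi-task neuroimaging feature data with
**independent vector analysis** (IVA), in constrained and transposed forms,
plus the stability-selection and group-statistics machinery needed to turn a
decomposition into group-difference findings.

## Who this is for

Analyses that start from K subject-by-voxel feature matrices — one per task
or modality, same subjects throughout — and ask: *which spatial patterns are
shared across tasks, how strongly does each subject express them, and do
patients and controls differ in that expression?* ICA answers this one
dataset at a time; IVA answers it jointly, linking the n-th component of
every dataset into a **source component vector** (SCV) and exploiting the
dependence within each SCV while keeping different SCVs independent.

## The model

Each reduced dataset follows `x[k](v) = A[k] s[k](v)` for datasets
`k = 1..K` at samples (voxels) `v = 1..V`. IVA-G estimates K demixing
matrices `W[k]` by minimizing the Gaussian maximum-likelihood cost

    J(W) = 1/2 * sum_n log det(Sigma_n)  -  sum_k log |det W[k]|

where `Sigma_n` is the K x K sample covariance of the n-th SCV (the additive
Gaussian constant is dropped). Only second-order statistics enter.

Two extensions are first-class here:

- **Threshold-free constraints.** Given references `r_1..r_M` (spatial maps
  or behavioral scores), the regularizer
  `J_ref = sum_n sum_k [ sum_{m != n} eps^2(r_n, s_m[k]) - eps^2(r_n, s_n[k]) ]`
  (with `eps` the Pearson correlation) is added as `J + (lambda/2) J_ref`,
  pulling component n toward reference n and pushing the other components
  away — no correlation threshold parameter involved.
- **Transposed IVA (tIVA).** Transposing each dataset swaps the roles of
  spatial maps and subject profiles: PCA acts on the voxel axis, the
  estimated sources *are* subject profiles, and behavioral scores can
  constrain them directly. The price is the sample-poor regime (samples =
  subjects), which is exactly where an informative constraint helps most.

Supporting layers: per-dataset PCA + whitening, repeated seeded runs with
**cross-joint-ISI** stability selection (the most reproducible run wins),
model-order scans, pooled two-sample t-tests with Benjamini–Hochberg FDR and
Cohen's d on the profiles, NIfTI-1 export of component maps, and a seeded
synthetic multi-task generator with known ground truth (SCV-structured
Gaussian sources, injectable group effects, tunable-fidelity references).

## Worked example

Simulate a 3-task study (120 subjects, 60/60 groups, 5000 voxels, 6
components) where component 1 carries a group effect of d = 0.8, then
recover that effect with a fidelity-0.8 behavioral reference through
constrained tIVA:

```r
library(ivafuse)

cfg <- synthetic_config(effect_sizes = c(0.8, 0, 0, 0, 0, 0), seed = 42)
sim <- synthesize_multitask(cfg)
ref <- make_noisy_reference(sim$truth, component = 1, fidelity = 0.8,
                            kind = "behavioral")
res <- run_constrained_tiva(sim$datasets, ref, order = 6,
                            opts = optimizer_options(seed = 1), lambda = 100)
res
#> <tiva_result> K=3 N=6, 120 subjects, constrained component 1

stats <- component_group_stats(lapply(res$profiles, t),
                               sim$truth$group_labels)
subset(stats, component == 1)
#>     task component    t        p    p_adj     d significant
#> 1  task1         1 4.27 3.94e-05 0.000237 0.780        TRUE
#> 7  task2         1 2.29 2.40e-02 0.047944 0.418        TRUE
#> 13 task3         1 1.28 2.03e-01 0.367164 0.234       FALSE

reference_correlation_table(res, reference_set(ref, "LNS"))
#>    task reference component abs_correlation
#> 1 task1       LNS         1           0.793
#> 2 task2       LNS         1           0.252
#> 3 task3       LNS         1           0.256
```

Reading the output: the constrained profile (component 1) recovers the
injected effect where the reference is informative — the estimated Cohen's d
in task 1 is 0.78 against the injected 0.8, FDR-significant at `p_adj =
2.4e-4` across the 6-component family. The correlation table is the
post-analysis check of reference quality: 0.79 in task 1 (the reference was
built from task 1's true profile at fidelity 0.8) and ~0.25 in the other
tasks, reflecting their weaker SCV coupling to component 1.

The same machinery runs end to end from the command line via
`inst/cli/ivafuse.R` with a JSON config (`mode`: `simulate`, `iva`, `civa`,
`tiva`, `ctiva`, `order-scan`, `evaluate`); see `?run_pipeline`.

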