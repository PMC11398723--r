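# ednet

Multi-echo fMRI connectivity analysis at desk scale: is the "limbic
network" a distinct system, or part of an extended default network?

## The problem

Resting-state parcellations place orbitofrontal cortex (OFC) and the
temporal pole / ventral anterior temporal lobe (TP/vATL) in a standalone
"limbic" network (LIM_A, LIM_B in 17-network nomenclature). These regions
sit next to the nasal airways, suffer susceptibility-related signal
dropout (short T2\*), and have poor temporal signal-to-noise (TSNR) in
single-echo fMRI — so their network assignment may be an artifact of bad
signal rather than real functional segregation. Multi-echo fMRI reads the
signal at several echo times (TEs), which allows (a) a TSNR-optimal
combination of echoes that rescues ventral signal, and (b) biophysical
denoising: fluctuations whose percent amplitude grows with TE behave like
transverse-relaxation (ΔR2\*, BOLD-like) effects, while TE-flat
fluctuations behave like baseline-intensity (ΔS0, artifact-like) effects.

`ednet` implements the full analysis pipeline that turns this idea into a
network-membership test, plus a synthetic multi-echo cohort generator with
planted ground truth, so every stage is verifiable end to end:

1. **Simulation** (`simulate_cohort`): mono-exponential decay
   `S_e = S0·exp(−TE_e/T2*)·(1 + (TE_e/30)·cR2 + cS0) + noise` with
   region-specific S0/T2\* (ventral dropout), latent network time courses,
   TE-flat artifact sources, motion with optional spikes, and a switch
   (`scenario = "merged"` vs `"distinct"`) controlling whether limbic
   parcels load on default-network latents or on a private latent.
2. **Signal quality** (`compute_tsnr`, `fit_monoexponential`,
   `optimal_combine`): log-linear T2\* fits and the classical
   TSNR-optimal weights `w_e ∝ TE_e · exp(−TE_e/T2*)`.
3. **TE-dependence denoising** (`denoise_run`): seeded ICA (echo-stacked),
   per-component κ (ΔR2\* fit) and ρ (ΔS0 fit) scores, BOLD iff κ > ρ,
   and the retained-BOLD coefficient set (MEFC) whose column count is the
   connectivity degrees of freedom.
4. **QC** (`framewise_displacement`, `dvars`, `apply_exclusions`): the
   four exclusion rules — FD > 0.5 mm *coupled with* DVARS > 1 at the
   same frame, median TSNR < 50, fewer than 10 BOLD components,
   coregistration failure.
5. **Connectivity** (`rsfc_from_mefc`, `group_mean_matrix`):
   parcel-by-parcel correlation of MEFC coefficients with the
   df-adjusted Fisher transform `Z = arctanh(R)·sqrt(df − 3)`.
6. **Community detection** (`louvain`, `infomap_partition`,
   `modularity_q`, `map_equation_codelength`): γ-resolution Louvain
   modularity warm-started from 7-network labels, and a two-level
   map-equation minimiser.
7. **Subnetwork clustering** (`eta_squared`, `similarity_matrix`,
   `ward_cluster`, `cut_dendrogram`): η² similarity of limbic whole-brain
   connectivity profiles, Ward (error-sum-of-squares) dendrograms,
   explicit cuts with height-gap diagnostics.
8. **Maps** (`one_sample_map`, `paired_contrast_map`, `bonferroni_mask`,
   `top_fraction_mask`, `network_profile`): mass-univariate t maps with
   Bonferroni and absolute-top-10% thresholds, and 17-network /
   subcortical profiles.

## Worked example

```r
library(ednet)

cohort <- simulate_cohort(6, "merged", master_seed = 42)
pipe   <- run_pipeline(cohort, seed = 1)
pipe
#> Pipeline result: 6 subjects ( 6 kept ), 109 parcels

part <- louvain(pipe$group, gamma = 1,
                init_labels = yeo7_init(cohort$atlas), seed = 1)
part
#> Partition (louvain): 7 modules over 109 nodes; Q = 0.488 (gamma = 1)

lim <- which(cohort$atlas$is_limbic)
dn  <- which(cohort$atlas$network_label %in% c("DN_A", "DN_B", "DN_C"))
mean(part$assignment[lim] %in% unique(part$assignment[dn]))
#> [1] 1

sim    <- similarity_matrix(pipe$matrices, lim)
labels <- cut_dendrogram(ward_cluster(sim), k = 3)
table(labels, cohort$truth$planted_lim_clusters)
#>       labels 1 2 3
#>            1 4 0 0
#>            2 0 4 0
#>            3 0 0 4
```

Despite the warm start keeping limbic parcels in their own module, every
limbic parcel ends up in a module containing default-network parcels
(fraction = 1): in the "merged" generative world the data pull them in.
The η²/Ward step then recovers the three planted limbic sub-clusters
exactly (each aligned with one DN subnetwork latent). Rerunning with
`scenario = "distinct"` keeps the limbic module separate at every γ.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the whole pipeline from scratch on a freshly simulated
12-subject merged cohort — echo combination, TE-dependence denoising, QC,
group MEFC connectivity, Louvain at γ ∈ {1, 1.25, 1.5}, map-equation
partitioning, η²/Ward clustering at k = 3, and Bonferroni/top-10%
connectivity maps — logging each stage's summary and writing the report
JSON to `--out`.
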