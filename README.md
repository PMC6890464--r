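# atacdyn

Downstream analysis of ATAC-seq depletion experiments for pioneer
transcription factors — the OCT4/SOX2 setting in mouse embryonic stem
cells is the motivating design. Given region-by-sample fragment counts
from inducible-depletion experiments (Tet-Off, mitotic degron, or
auxin-inducible degron), `atacdyn` provides the full inference chain:

1. **Peak preprocessing** — BED interval handling with 0-based half-open
   coordinates: merging (book-ended intervals merge at gap 0), removal of
   peaks longer than 5 kb, blacklist/Input exclusion, ±pad expansion,
   nearest-TSS annotation with a distal (>1 kb) / proximal (≤1 kb) split.
2. **Normalization** — trimmed-mean-of-M-values (TMM) scaling factors
   (trim 30% on M, 5% on A, inverse-variance weights, geometric mean 1)
   and log2-CPM with a half-count prior.
3. **Differential accessibility** — per-region ordinary least squares on
   log2-CPM under a no-intercept condition + replicate-batch design
   (`~ 0 + Condition + Replicate`), empirical-Bayes variance moderation
   (`s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)`, with `d₀`, `s₀²` estimated by
   moment matching on `log s²_g`), moderated t statistics, and
   Benjamini–Hochberg FDR.
4. **Dependency classification** — direction-consistency filtering of
   significant changes across paired comparisons (26 h vs 40 h
   depletion, or two culture settings), exclusion of regions with
   baseline differences (FDR < 0.05 and FC > 4), a ChIP-binding gate, and
   labelling as OCT4-dependent (OD), SOX2-dependent (SD), co-dependent
   (CD) or gained, with per-label binding-overlap fractions.
5. **Cell-cycle dynamics** — region-by-phase (EG1/LG1/S/SG2) log2
   fold-change matrices, euclidean k-means (k = 4, k-means++ with
   restarts, deterministic under a seed) with clusters ordered by
   ascending mean EG1 fold-change.
6. **Kinetics** — three-parameter exponential decay fits
   `y = a·e^(−bt) + c` with half-life `ln 2 / b`, applied to single-cell
   fluorescence degradation traces (population average and per cell) and
   to TMM-normalized accessibility time courses per cluster.

A negative-binomial synthetic-data generator
(`simulate_depletion_experiment()`, `simulate_cellcycle_experiment()`,
`simulate_timecourse()`, `simulate_traces()`) emulates all supported
designs with known ground truth, so every stage is testable without
sequencing data.

## Worked example

```r
library(atacdyn)

sim  <- simulate_depletion_experiment(sim_params(seed = 1))
norm <- tmm_factors(sim$counts)
fit  <- ebayes_moderate(fit_linear_model(log2_cpm(sim$counts, norm),
                                         make_design(sim$samples)))
oct4 <- consistent_changes(contrast_fit(fit, "ZHBTc4_SL_dox",   "ZHBTc4_SL_untr"),
                           contrast_fit(fit, "ZHBTc4_S2iL_dox", "ZHBTc4_S2iL_untr"),
                           tf = "OCT4")
sox2 <- consistent_changes(contrast_fit(fit, "2TS22C_S2iL_dox26", "2TS22C_S2iL_untr"),
                           contrast_fit(fit, "2TS22C_S2iL_dox40", "2TS22C_S2iL_untr"),
                           tf = "SOX2")
excluded <- baseline_exclusion(list(
  contrast_fit(fit, "ZHBTc4_SL_untr",   "ZHBTc4_S2iL_untr"),
  contrast_fit(fit, "ZHBTc4_S2iL_untr", "2TS22C_S2iL_untr")))
bound <- bound_region_ids(sim$regions, sim$oct4_peaks, sim$sox2_peaks)
call  <- classify_dependency(oct4, sox2, sim$regions$id, excluded, bound)
call
#> dependency_call over 5000 regions:
#>                  CD   excluded_baseline    excluded_unbound gained_on_OCT4_loss
#>                 212                  28                  12                 603
#> gained_on_SOX2_loss                  OD                  SD        unclassified
#>                  15                 524                 135                3471
binding_overlap_report(call, sim$oct4_peaks, sim$sox2_peaks, sim$regions)
#>                 label   n frac_oct4  frac_sox2
#> 1                  OD 524 0.9980916 0.64503817
#> 2                  SD 135 0.8814815 0.99259259
#> 3                  CD 212 1.0000000 1.00000000
#> 4 gained_on_OCT4_loss 603 0.2106136 0.09784411
#> 5 gained_on_SOX2_loss  15 0.3333333 0.06666667
```

The call recovers the planted structure: 500/150/250 OD/SD/CD regions
were simulated, and the overlap fractions reproduce the generator's
planted binding rates (SD sites overlap an OCT4 peak at ~0.89, OD sites
a SOX2 peak at ~0.65; OD/CD sites are fully OCT4-bound).

Degradation kinetics from simulated single-cell traces:

```r
tr <- simulate_traces(sim_params(seed = 1))     # 45 cells, rate 2.166/hr
fit_trace_halflife(tr$traces)$population
#> decay_fit: y = 1075 * exp(-2.178 t) + 1.361
#>   half-life 0.318 hr | rss 476.5 | 21 points | converged: TRUE
```

The fitted half-life (0.318 hr) recovers the planted ln 2 / 2.166 =
0.32 hr.

`run_pipeline(pipeline_config(seed = 1), out_dir = "out")` chains all of
the above (plus clustering and the inhibitor time course) and writes
TSV/BED/JSON outputs with the resolved configuration; a command-line
wrapper is in `inst/scripts/atacdyn-pipeline.R`.

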