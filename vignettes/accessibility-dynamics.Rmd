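---
title: "Models and methods: differential accessibility, dependency classification, and decay kinetics"
author: "atacdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacdyn)
```

# Scope

`atacdyn` implements the downstream inference chain for quantifying how
pioneer transcription factors control chromatin accessibility: from
region-by-sample ATAC fragment counts to (i) differential-accessibility
calls, (ii) a factor-dependency classification of regulatory elements,
(iii) clusters of cell-cycle accessibility dynamics, and (iv)
exponential-kinetics estimates of accessibility-loss and
protein-degradation half-lives. Read alignment, peak calling, track
generation and motif analysis are upstream/downstream of this package
and out of scope; the entry points are BED peak/fragment files or count
tables plus a sample sheet.

# Interval preprocessing

All coordinates are 0-based half-open (the BED convention) in every
user-facing structure; conversion to the 1-based closed representation
used by `GenomicRanges` happens internally and is invisible to callers.
The preprocessing rules mirror standard ATAC practice:

* peak sets are merged with book-ended intervals (end == next start)
  unioned at `gap = 0`, the default of the common merge tools;
* "peaks larger than 5 kb" is interpreted strictly: length > 5000 is
  removed, exactly 5000 is kept;
* exclusion (blacklist or Input-sample peaks) drops a region on any
  shared base; `[10,20)` and `[20,30)` share none;
* nearest-TSS distances are unsigned gap distances (0 when the TSS lies
  inside the region). The tie between equidistant TSS on both sides is
  broken toward the smaller genomic coordinate, which makes the
  annotation deterministic; distances are classified distal (> 1 kb) or
  proximal (≤ 1 kb).

Chromosome names are compared as exact strings; no "chr" prefix
normalization is attempted.

Fragment counting assigns each fragment to the unique merged region
containing its midpoint `floor((start + end)/2)`. Midpoint assignment
(rather than any-overlap, which is available behind `mode = "any"`)
guarantees a fragment is never counted twice across adjacent merged
peaks, at the cost of dropping fragments straddling a region edge.
Whether an upstream counter counted reads or fragments is generally
tool-specific; this package counts fragments, and the difference only
rescales library sizes, which normalization absorbs.

# Normalization and the moderated linear model

Between-sample scaling uses the trimmed mean of M-values (TMM). For
sample $k$ against the reference $r$ (the sample whose 75th percentile
of count/library-size is closest to the mean of those percentiles),
over regions with positive counts in both:

$$M_g = \log_2\frac{Y_{gk}/N_k}{Y_{gr}/N_r},\qquad
  A_g = \tfrac12 \log_2\left(\frac{Y_{gk}}{N_k}\cdot\frac{Y_{gr}}{N_r}\right),\qquad
  v_g = \frac{N_k - Y_{gk}}{N_k Y_{gk}} + \frac{N_r - Y_{gr}}{N_r Y_{gr}}.$$

The top and bottom 30% by $M$ and 5% by $A$ are trimmed and the factor
is the inverse-variance weighted mean
$\log_2 f_k = \sum M_g / v_g \Big/ \sum 1/v_g$ over the survivors,
rescaled so the factors have geometric mean one. The inverse-variance
(delta-method) weighting is the published form of the method; the test
suite verifies equality with an independent reference implementation to
1e-10. A consequence worth knowing: scaling one column's counts and
library size by a constant rescales one term of $v_g$, so factors are
invariant to pure depth changes only to ~1e-3, not exactly.

Testing operates on $\log_2$-CPM,
$\log_2\!\big((Y + 0.5) / (N_k f_k + 1) \cdot 10^6\big)$, in the
limma-trend spirit: per-region ordinary least squares under a
no-intercept design with one indicator per condition plus
replicate-batch indicators (`~ 0 + Condition + Replicate`), which
absorbs the paired structure of depletion experiments performed in
batches. No precision weights are applied — the supported designs use
deeply covered consensus peaks where the mean–variance trend is mild —
and this is noted as the main divergence from weighted variants.

Empirical-Bayes moderation assumes the scaled inverse-$\chi^2$ prior
$\sigma_g^2 \sim s_0^2 d_0 / \chi^2_{d_0}$. The hyperparameters are
estimated by moment matching on
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$: solve
$\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d_g/2)$ by Newton iteration on
the trigamma inverse (start $d_0 = 10$, tolerance 1e-8, at most 50
iterations; non-convergence or non-positive target yields
$d_0 = \infty$, i.e. complete shrinkage), and
$s_0^2 = \exp(\bar e + \psi(d_0/2) - \log(d_0/2))$. Moderated variances
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ give moderated t
statistics on $d_0 + d_g$ degrees of freedom. Regions with zero counts
everywhere are excluded before fitting. FDR control is
Benjamini–Hochberg per contrast (not across contrasts), mirroring
per-comparison calls.

# Dependency classification

The classifier formalizes a multi-step rule:

1. **Consistency** — a region is a candidate change for a factor when
   significant (q < 0.05) in at least one of that factor's two
   comparisons (`mode = "any"`, default) and its fold-change has the
   same non-zero sign in both. The alternative `mode = "both"`
   (significance required in both) is available; "any" was chosen as the
   default because the two comparisons per factor differ deliberately in
   sensitivity (shorter/longer depletion, different culture), so
   requiring joint significance discards real responders detected by
   only the better-powered comparison.
2. **Baseline exclusion** — regions already differing between untreated
   baselines (culture settings or cell lines) are removed when
   significant *and* |log2FC| > 2 (FC > 4; equality retained). The joint
   condition follows the two-step phrasing of first calling significant
   baseline differences and then discarding the large ones.
3. **Binding gate** — decreased regions must overlap (≥ 1 bp) the merged
   OCT4/SOX2 ChIP peak universe; unbound decreases are labelled
   `excluded_unbound`. Gained regions are not gated on binding, since
   accessibility gains are largely factor-unbound, but are subject to
   the baseline exclusion.
4. **Labels** — decreased in one factor's set only → OD or SD; in both →
   CD; increases → `gained_on_*` (decreases take precedence when a
   region decreases under one factor and increases under the other;
   OCT4 before SOX2 when gained under both). Every region of the
   universe receives exactly one label.

# Cell-cycle clustering

The region-by-phase matrix holds the per-phase contrast log2
fold-change (degron vs control within each sorted fraction), with
columns fixed in cell-cycle order EG1, LG1, S, SG2. Clustering is
euclidean k-means with k = 4, Lloyd iterations, k-means++ seeding, and
10 restarts keeping the lowest within-cluster sum of squares. The
published tool's initialization is unstated, so determinism is
prioritized: a recorded seed makes the whole path bit-reproducible.
Clusters are relabelled so that mean EG1 fold-change ascends — cluster 1
is the strongest early-G1 loser — with ties broken by cluster size
(larger first).

# Decay kinetics

Both protein-degradation traces and accessibility time courses are fit
with the three-parameter exponential $y = a e^{-bt} + c$, and half-life
$\ln 2 / b$. Numerical choices:

* $b$ is kept positive through an internal log parameterization
  ($b = e^{\lambda}$); a generic unconstrained fitter can wander into
  $b \le 0$ on noisy plateaus, and a negative rate has no kinetic
  meaning here. The offset $c$ is unconstrained, accounting for residual
  ATAC signal or fluorescence background.
* Initialization: $c_0 = \min(y) - 0.05\,\mathrm{range}(y)$ (strictly
  below the minimum so logs are defined), then a log-linear regression
  of $y - c_0$ on $t$ supplies $a_0$ and $b_0$. Data whose log-linear
  slope is non-negative raise "no decay detected" — as observed for
  cluster-4-like loci insensitive to factor loss.
* Optimization is Levenberg–Marquardt (`minpack.lm::nls.lm`) on the raw
  residuals with `ftol` 1e-12, `ptol` 1e-10, at most 500 iterations;
  noiseless data are recovered to 1e-6 relative error and
  non-convergence is reported via a `converged` flag rather than an
  error.
* Accessibility time courses aggregate as: TMM-normalize → average
  CPM over replicates per time point → average over the cluster's
  regions, in that order, then fit within the 0–4 h window (later
  points mix in indirect effects). Single-cell traces are fit both as a
  population average (the headline estimate — it suppresses the
  multiplicative single-cell noise) and per cell, since it is ambiguous
  which a given figure reports; both are returned.

# The synthetic-data generator

The generator replaces deposited sequencing data for building and
testing. It emulates, per design:

* **Dual depletion** (`simulate_depletion_experiment`): seven
  conditions — ZHBTc4 ± dox in SL and S2iL media, 2TS22C untreated and
  dox for 26/40 h — in replicate batches, counts
  $Y \sim \mathrm{NB}(\mu = N_k f_k\, 2^{\beta_g + \delta},\ \phi)$ with
  a single global dispersion $\phi = 0.05$ (the simplest model of ATAC
  overdispersion the testing stage must tolerate), baseline log2-CPM
  $\sim \mathcal N(5, 1)$ over a 2 × 10 Mb toy genome (region widths
  200–1000 bp), library sizes log-normal around $3\times10^6$ (cv 0.2),
  and hidden log-normal composition factors (sd 0.1) so TMM has
  something non-trivial to estimate. Planted classes: OD/SD/CD lose
  1.5 log2 units under the relevant depletion(s), "gained" regions gain
  1.5 under OCT4 loss, nulls are flat; 2% of regions carry a ±2.5 log2
  baseline culture/cell-line shift to exercise the exclusion filter.
  ChIP peaks are planted at rates mirroring the reported binding
  overlaps (OCT4 at 100% of OD/CD and 89% of SD; SOX2 at 100% of SD/CD
  and 65% of OD; background rates at gained/null regions).
* **Cell cycle** (`simulate_cellcycle_experiment`): four template
  profiles over EG1/LG1/S/SG2 — strong EG1 loss with partial recovery
  (−2.8, −1.8, −1.2, −1.0), moderate loss with full recovery
  (−1.6, −0.8, −0.3, 0), small persistent loss (−0.7 across), and flat —
  with per-region jitter (sd 0.1) and dispersion 0.02, reflecting the
  lower biological variability of sorted fractions at bound sites and
  keeping the planted separation at roughly five within-cluster
  standard deviations, the regime the clustering recovery tests assume.
* **Inhibitor time course** (`simulate_timecourse`): responsive regions
  decay as $m(t) = (m_0 - c)e^{-bt} + c$ with $b = 1.386\,h^{-1}$ and a
  30% plateau; 10% of regions are responsive so that normalization
  retains a stable majority of unchanged regions (if every region
  decayed, TMM would absorb the decay itself).
* **Traces** (`simulate_traces`): 45 cells sampled every 0.1 h for 2 h,
  $y_i(t) = A_i e^{-bt}(1 + \varepsilon)$ with $b = 2.166\,h^{-1}$,
  log-normal amplitudes (cv 0.3) and 10% multiplicative Gaussian noise.

What the generator does **not** emulate: GC/accessibility-dependent
trends in dispersion, correlated noise between neighbouring regions,
read-level artefacts (duplicates, Tn5 sequence bias), mappability, or
per-region dispersion heterogeneity (a per-region option exists but the
default is global). Passing the recovery tests therefore demonstrates
correctness of the inference chain under a clean negative-binomial
world, not robustness to every artefact of real libraries.

# Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale: 5,000
regions for classification (10,000 for null calibration), 2,000 for
clustering recovery, ~500 responsive loci for the time course, 45 cells
for traces — sizes chosen so the full suite completes in well under a
minute while keeping binomial/Monte-Carlo error comfortably inside the
asserted tolerances. Every stochastic path takes an explicit seed; the
simulate → normalize → test → classify/cluster/fit chain is
bit-reproducible given (configuration, seed).

# Known limitations

* Differential testing is normal-theory on log2-CPM; very low counts
  (< ~10 fragments) are better served by count likelihoods, which are
  deliberately out of scope here.
* The empirical-Bayes prior is global (no abundance trend, no robust
  down-weighting of variance outliers); with a strong mean–variance
  trend the moderated t can be mildly miscalibrated at the extremes.
* The classifier's `mode = "any"` default makes detection power depend
  on the better of the two comparisons; users wanting symmetric
  stringency should use `mode = "both"`.
* Single-contrast power at the default generator coverage is ~80% for a
  1.5 log2-unit effect with two replicates; the two-comparison rule is
  what achieves ≥90% recovery.
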