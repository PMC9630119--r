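---
title: "Methods: models, parameters and design choices in wmglia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in wmglia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmglia)
```

# Scope

`wmglia` implements the computational core of a single-cell and spatial
analysis of white matter aging: aging murine white matter accumulates
CD8+ T cells, and in their vicinity oligodendrocytes and microglia adopt
interferon-responsive states (IRO and IRM, marked by Stat1, Ifi27l2a,
B2m, MHC-I genes and Ifit3), alongside a more abundant age-related
oligodendrocyte state (ARO, marked by Serpina3n and C4b). The package
provides four analysis stages — per-cell QC filtering, signature-based
cell-state assignment with marker ranking, compositional change testing,
and spatial proximity analysis with a random-cell null — plus a
synthetic-data generator that plants known ground truth for every stage,
so that calibration and power are measurable properties of the shipped
code rather than claims.

Deliberately out of scope: variance-stabilising normalisation internals,
graph clustering and embeddings, dataset integration, GO enrichment, and
anything upstream of a count matrix (alignment, demultiplexing). Where a
published workflow used such tools, this package substitutes documented,
simpler stages and says so below.

# QC filter chains

**Smart-seq2.** Nine per-cell metrics, each with a closed interval
`[lo, hi]`; a cell passes iff every metric is inside its interval,
bounds inclusive (the thresholds are written as ">=" / "<=" in the
originating workflow, so 20,000 reads exactly passes). Defaults:
reads `[2e4, 4e6]`, genes `[1000, 6500]`, mean trimmed read length
`[180, 200]` bases, alignment mismatch rate `[0.15, 0.5]`, unique
mapping `[68, 100]`%, multimapping `[2.3, 7.7]`%, too-short reads
`[0, 17]`%, ERCC fraction `[0, 0.011]`, mitochondrial fraction
`[0, 0.006]`. Two printed conventions are unusual and are applied as
printed rather than silently "corrected": the mismatch-rate interval has
a lower bound, and the ERCC/mitochondrial bounds are read on the 0-1
fraction scale (both are plain arguments of `smartseq_thresholds()`, so
either reading is available).

**Droplet.** Gene filter first (a gene must be detected in at least 3
cells), then cell filters with strict caps: fewer than 200 detected
genes removed, mitochondrial fraction strictly above 0.10 removed, UMI
and gene counts at or above the per-batch caps removed. The order
matters — the gene filter changes detected-gene counts — so it is fixed
and tested. The per-batch UMI/gene caps (30k/6k, 50k/8k, 20k/none,
25k/8k in the originating batches) are configuration, not code.

# Count simulation

`generate_counts()` draws gamma-Poisson (negative binomial) counts:
per-gene base means from a long-tailed lognormal (`meanlog = log(0.3)`,
`sdlog = 1.2`), per-cell library-size factors lognormal
(`sdlog = 0.3`), NB dispersion 0.3 — values in the range routinely
estimated from droplet scRNA-seq. Each cell's state multiplies that
state's marker means by the profile's fold factor (default 8). Marker
genes get a base mean of 2 counts, i.e. a clearly expressed gene; the
designated mitochondrial genes, the rRNA-contamination indicators
`Gm42418`/`AY036118`, and (for plate-based cells) ERCC spike-in features
are always present.

The default condition is an aged white-matter mixture of
Oligo1/ARO/IRO/CD8_T at proportions 0.40/0.25/0.20/0.15. Two choices
here are deliberate and worth spelling out. First, signature scores are
means of across-cell z-scores, and a z-score's separation between a
"high" and a "low" group degrades as the mixture becomes one-sided: for
a state occupying fraction p of cells, the high group sits about
`sqrt((1-p)/p)` standard deviations above the mean in the ideal
noise-free case, which crosses the assignment threshold region once p
is large. A 40% baseline state is comfortably identifiable; an 85%
baseline state is not, and the gray-matter default (0.85 Oligo1) is
kept to model exactly that harder regime. Second, the baseline state
carries a realistic eight-gene canonical myelin panel (Plp1, Mal, Mog,
Cldn11, Mbp, Mobp, Cnp, Ptgds) because averaging more marker z-scores
shrinks score noise by `1/sqrt(k)`; two-gene signatures (ARO, T/NK) are
kept as published and remain identifiable because those states are
minorities.

What the generator does **not** emulate: ambient RNA, doublets,
batch effects, gene-gene correlation beyond the state structure, or
zero inflation beyond the NB. Passing recovery tests therefore shows
the assignment machinery is correct and well-calibrated on clean
planted structure — not that 95% accuracy is attainable on real tissue.

# Signature scoring and state assignment

Counts are log-normalised (`log(1 + 1e4 * count/libsize)`). A
signature's per-cell score is the mean across its genes of the gene's
across-cell z-score; zero-variance genes contribute 0 (avoiding NaN),
absent genes are dropped with a note. A cell is assigned the
highest-scoring signature strictly above its threshold, ties broken by
rule order; otherwise `"unassigned"`. The threshold (default
`tau = 0.5` z-units) is an analysis parameter of this package: the
originating study derived states from graph clustering, which defines
no numeric score cut, so no published value exists to inherit.

Marker ranking uses the two-sided Wilcoxon rank-sum test per gene:
exact enumeration over all assignments of the observed ranks when both
groups have at most 10 cells (tie-safe by construction), otherwise the
normal approximation with tie and continuity correction. The effect
size is `avg_log2FC = log2((mean(expm1 A) + 1e-9)/(mean(expm1 B) +
1e-9))`; the `1e-9` pseudo-expression matches common practice for this
kind of workflow. BH adjustment runs across all tested genes before
any fold-change filtering, and the conventional marker cut is
`|avg_log2FC| > 1`.

# Compositional testing

Per-sample state counts are summarised as proportions; boxplot
summaries use type-7 (linearly interpolated) quartiles with the
1.5×IQR whisker/outlier convention, matching the plotting convention of
the field.

The change test is a beta-binomial likelihood-ratio test of
state-vs-rest counts: shared overdispersion, one group probability
under the null versus two under the alternative, both fitted by
maximum likelihood (Nelder-Mead on logit/log scales), LR referred to
chi-squared with 1 df, BH across states, flagged at FDR 0.4 by default.
The 0.4 default mirrors the permissive setting used for compositional
screens designed to catch subtle but biologically relevant shifts; for
confirmatory use, pass a conventional 0.05. The state-vs-rest framing
avoids choosing a reference cell type, a choice the original
compositional analysis left unstated.

Known limitation: at 10 samples per group the LRT is mildly
anti-conservative — simulated type-I error at nominal 0.05 is about
0.06-0.09 depending on the replicate stream, i.e. around 1.2-1.7 times
nominal. The power of the test against a 3-fold shift of a 5% state
(1,000 cells/sample) is essentially 1. Effect signs are reported as
second-group-minus-first with groups in order of appearance.

# Proximity analysis

Distances are Euclidean between cell centres within a section; a
subject "has a neighbour" if its nearest neighbour-category cell is at
distance `<= radius` (default 20 micrometres, boundary inclusive — the
drawn circle of radius 20 is taken to include its rim). Two search
backends, a bucketed grid index and brute-force all-pairs, are required
to agree exactly and are tested against each other.

The null replaces the neighbour set by randomly sampled DAPI+ nuclei of
matched per-section count, excluding the neighbour category itself and
(by default, configurable) the subject category. Rather than a single
manual random selection, `n_null_draws = 100` seeded draws are averaged
per mouse — a strictly more stable estimator of the same null;
`n_null_draws = 1` reproduces the one-shot procedure. Per-mouse
fractions pool cells across the mouse's sections by default
(`aggregation = "section_mean"` is available since the original
reporting granularity is ambiguous). Observed and null per-mouse
fractions are compared with a classical two-sided paired t-test.

No edge correction is applied (none was applied in the source
procedure). For the analytic calibration check against the Poisson
formula `1 - exp(-lambda * pi * r^2)`, the package's tests erode the
window by one radius and evaluate only interior subjects, which removes
boundary bias exactly instead of bounding it.

The subregional comparison classifies sections as frontal (no lateral
ventricles) versus medial (bordering the ventricles) white matter,
averages section values within mouse and region, and applies the paired
t-test across mice.

**Spatial generator defaults.** 600×600 micrometre window, 11 reference
(CD8) and 23 target (IRO) cells per section, background DAPI intensity
1e-3 per square micrometre (~360 nuclei/section), 4 mice × 3 sections —
per-section counts scaled from a study quantifying 134 CD8+ T cells and
272 IRO cells over 4 mice × 3 sections. No field-of-view size was
published, so the window is an explicit configurable guess; with a
planted association the generator places targets near a uniformly
chosen reference parent with an isotropic Gaussian displacement
(default sigma 8 micrometres), re-sampling any out-of-window offspring
rather than clamping them (clamping would pile cells on the boundary
and bias proximity fractions).

# Numerical and degenerate-input conventions

* Every generator is a pure function of its arguments including the
  seed; seeds are applied locally and the caller's RNG state restored.
* Pipeline stage seeds derive from one global seed by a fixed affine
  map (`derive_seed`), so stages can be re-run independently.
* Zero-libsize cells are an error in `normalize_log` (they signal
  skipped QC), not silently zeroed.
* A state absent from all samples, or comprising 100% of every sample,
  is skipped by `test_composition` with a note.
* Paired tests with all-zero differences return `t = 0, p = 1`;
  non-zero constant differences return infinite `t`, `p = 0`.
* An absent neighbour category yields proximity fraction 0; an absent
  subject category is an error.

# Problem sizes used in the shipped checks

The package's own test suite runs its heaviest experiments at: 10,000
cells for QC oracle equivalence; 100 random patterns for grid/brute
equivalence; 200 simulated studies for spatial-null calibration and 100
for power; 500 Dirichlet-multinomial null simulations and 100 power
replicates for the compositional test; 2,000 cells for state recovery.
These sizes give Monte-Carlo standard errors comfortably below the
margins being checked while keeping a full run in the low minutes on a
single core.

# Known limitations

* The compositional LRT's small-sample anti-conservatism (above).
* Signature-threshold assignment is not a clustering method: states
  must be describable by their marker panels, and a dominant baseline
  state (>~70% of cells) approaches the z-score identifiability limit.
* The spatial model is 2-D and ignores section thickness; distances are
  centre-to-centre with no cell-size correction.
* The paired t-test at n = 4 mice relies on approximate normality of
  per-mouse fraction differences; its simulated null rejection rate
  (~0.05-0.08) sits at the permissive edge of the binomial band around
  the nominal level.
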