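---
title: "Classifying and integrating dehydration stress memory responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and integrating dehydration stress memory responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressmem)
```

## The problem this package addresses

Plants exposed to a sub-lethal dehydration stress respond differently when the
stress recurs: part of the transcriptome, and part of leaf physiology, carries
a *memory* of the first exposure. The experimental design this package
analyses samples a transcriptome at the watered state (W), after a first
dehydration stress (S1) and after a repeated stress, and measures physiology
per plant at W, S1, a rehydration stage (R1) and a second stress (S2).
Because selected genes respond near-identically in the second and third
stress, the repeated-stress transcriptome stage (S3 in the default design) is
treated as equivalent to the physiological S2 stage.

Every gene and every physiological parameter is summarised by a two-position
sign pattern. The first sign is the direction of a significant S1-vs-W
response, the second the direction of a significant repeated-stress-vs-S1
response; a non-significant contrast contributes `=`. The patterns partition
into four categories:

* **memory** — `[+/+] [+/-] [-/-] [-/+]`: the repeated-stress response differs
  significantly from the first response;
* **delayed memory** — `[=/+] [=/-]`: no first-stress response, a significant
  response only on repetition;
* **non-memory** — `[+/=] [-/=]`: a first-stress response repeated at similar
  magnitude;
* **non-responsive** — `[=/=]`.

## Differential-expression calls

A gene is significantly differential between two stages when all three of the
following hold (`run_config()` holds the thresholds):

1. BH-adjusted q-value at or below `q_threshold` (default 0.05);
2. |log2 fold change| at least `lfc_threshold` (default 1), where the fold
   change is computed between stage-mean FPKM values with a pseudocount of 1
   so that zero-FPKM genes keep a bounded fold change;
3. the expression floor: in at least one of the two stage profiles the gene
   must exceed that profile's `expr_percentile` (default 25th) percentile over
   all genes. Percentiles interpolate linearly between order statistics and
   the comparison is strict, so a gene sitting exactly on the floor fails.
   This removes genes whose "significant" change happens entirely inside the
   noise floor. Replicates are averaged per stage before the floor is
   evaluated, so the rule compares the two contrasted stage profiles.

The q-values of the internal path come from a per-gene two-sample t test on
log2(FPKM + 1) replicate values. We use the pooled-variance (Student) form by
default rather than Welch: with two replicates per stage, Welch's
Satterthwaite approximation yields between 1 and 2 degrees of freedom
depending on the ratio of the two sample variances, and the lost degrees of
freedom inflate p-values so strongly that even planted four-fold changes
essentially never survive FDR control (on the default simulation roughly 2 of
250 planted-effect genes were recovered). The pooled test holds 2 df
throughout and recovers about 97% of planted patterns. Welch remains
available (`var_equal = FALSE`) for designs with more replication, and
externally computed per-gene statistics (e.g. from a count-model DE tool) can
be supplied instead; the internal path is a transparent stand-in, not a
re-implementation of any specific RNA-seq pipeline, and its q-values will not
numerically match one.

An optional third gate — requiring that the second and third stress not
differ — is available (`classify_memory` via a dedicated external table) but
off by default, since with the default design those stages are already pooled
by the equivalence map.

## Co-expression modules

Genes whose FPKM range across all samples is at most `variation_min_range`
(default 0.05, strict) are removed; near-constant profiles carry no usable
correlation signal. The default dissimilarity is unsigned,
`d = 1 - |Pearson r|`, computed on log2(FPKM + 1) (variance stabilisation;
the correlation scale is otherwise dominated by the heavy right tail of
FPKM). A topological-overlap variant (`method = "tom"`, soft power 6 by
default) is available by flag; with only six samples we default to the plain
correlation for transparency.

Modules are branches of the average-linkage dendrogram, extracted by a
deterministic dynamic tree cut (the height-profile "tree" flavour, not the
PAM-assisted hybrid): starting at the root, a branch is accepted as a module
when

* it holds at least `min_module_size` genes (default 30),
* its merge height is at most `max_core_height`, and
* no relative height gap of at least `split_gap` (default 0.15) separates two
  children that could each stand as a module — if one does, both children are
  descended into instead.

Genes stranded in rejected branches form module 0 (unassigned). The decision
depends only on merge heights and sizes, so the cut is deterministic;
remaining label ties are broken by decreasing module size and then lowest
gene index.

`max_core_height` is the sensitive choice. With six samples the null
distribution of the correlation coefficient is wide — for unrelated genes
P(|r| > 0.9) is about 1.5% — so thousands of background genes generate an
abundance of spurious tight pairs, and average linkage happily assembles them
into clusters whose average |r| is far above what larger designs would call
high. Accepting a branch therefore demands within-module correlations well
above that spurious sea: the default 0.05 (within-module |r| around 0.95)
left planted 50-gene modules intact while rejecting noise clusters in our
simulations (adjusted Rand index 0.91-0.97 across seeds), whereas a
conventional-looking 0.25 admitted dozens of pure-noise modules (ARI 0.04).
This mirrors the practice of holding small-n co-expression networks to a
high correlation threshold.

The **eigengene** of a module is the first principal component of its
standardized expression: each gene's log2 profile is centred and scaled
across samples and the first right singular vector (unit norm) summarises the
module; its orientation is fixed to correlate non-negatively with the
module's mean standardized profile (with the largest-magnitude element made
positive in the zero-correlation tie case). Modules whose eigengenes are
mutually close — dissimilarity `1 - r` at most `metamodule_cut` (default
0.2) under average linkage — form meta-modules; a module distant from all
others stays a solo group.

## Enrichment

GO-term over-representation per module (or meta-module) uses the one-sided
hypergeometric tail `P(X >= k)` for the 2x2 table of term membership against
module membership — the over-representation direction only, matching how
such gene lists are usually screened. Terms annotating fewer than
`min_mapped_entries` (default 5) reference genes are not tested; the floor
applies to the reference mapping count K. FDR is BH-controlled within each
module's term list (per-gene-set testing convention; a global option exists).
Annotations are taken as provided — no GO-graph ancestor propagation is
performed, so propagate upstream if term closure is wanted. A slim mapping
can roll results up to coarse categories, reporting the minimum FDR per
(module, slim) cell for heatmap display.

## Physiology

Raw chlorophyll-fluorescence and gas-exchange readings are converted with the
standard quenching-analysis relations (Genty-style yields): φPSII =
(Fm′−Fs)/Fm′, Fv′/Fm′ = (Fm′−Fo′)/Fm′, qP = (Fm′−Fs)/(Fm′−Fo′), NPQ =
Fm/Fm′−1, ETR = φPSII × PPFD × `psii_fraction` × `absorptance` (defaults 0.5
and 0.85, both configurable), gross assimilation A_G = P_N + R_d (dark
respiration is a configuration input), φCO2 = A_G/(PPFD × absorptance), and
the composite ratios qE/ETR, φPSII/φCO2 and ETR/A_G. When Fo′ was not
measured it is estimated by the Oxborough-Baker relation
Fo/(Fv/Fm + Fo/Fm′). The identity φPSII = qP × Fv′/Fm′ holds to numerical
precision and is asserted in the tests.

Energy-dependent quenching is split off NPQ from a post-relaxation maximal
fluorescence `relaxed_Fm'`: qE = Fm/Fm′ − Fm/relaxed_Fm′ assumes fully
oxidised centres, and the quantum-yield form φqE = Fs/Fm′ − Fs/relaxed_Fm′
makes the opposite assumption. Without a relaxation measurement all NPQ is
attributed to qE and the output flags the assumption. These relaxation-based
definitions are our documented choice among the several in circulation.

Total chlorophyll is exactly (8.02·A663 + 20.2·A645)/DW in mg per g dry
weight. Chlorophyll means are classified with the same t-test scheme as every
other parameter; the original mixed-effects treatment of assay date as a
random intercept is deliberately simplified away.

Each parameter's memory pattern uses the same sign scheme as genes: Welch
t tests (default here, since variances genuinely differ across stress
stages and 10 plants per stage support the approximation; pooled-variance
Student available by flag) on per-plant values for S1 vs W and S2 vs S1 at
`alpha_phys` (default 0.05), uncorrected — matching the per-contrast
convention of the displayed comparisons.

## The synthetic-data generator

`simulation_spec()` plants ground truth that the pipeline should recover:

* **Expression.** Module genes share a latent stage profile on the
  log2(FPKM + 1) scale; each gene's values are `loading × profile(stage) +
  N(0, replicate_sd)` with a per-gene loading from N(1, `loading_sd`), then
  back-transformed (noise Gaussian in log space keeps FPKM non-negative and
  heavy-tailed). Background genes are i.i.d. noise around flat per-gene
  baselines. Defaults: 2000 genes, five 50-gene modules, two replicates per
  stage (mirroring the study design), replicate noise 0.1. Stage steps in
  the default profiles are 0 or ±2 log2 units — twice the fold-change
  threshold — and the five profile shapes keep pairwise |correlation| at or
  below 0.87, because an unsigned network cannot separate sign-flipped
  profiles. A spec whose profile contradicts its declared pattern (e.g. a
  `[=/+]` label with a first step of 2) errors before sampling.
* **Physiology.** Per-plant values are stage means plus Gaussian noise; the
  default plan encodes the qualitative memory calls observed for maize
  (g_s and E `[-/-]`, RWC and C_i `[-/=]`, ABA `[+/=]`, P_N and the PSII
  efficiency parameters `[=/-]`, the qE family `[=/+]`, chlorophyll
  `[-/-]`, composite ratios `[=/+]`), with magnitudes in the usual units for
  two-week maize seedlings. Stage means are *exactly* equal wherever a
  pattern carries `=`, so the zero-noise limit reproduces the planted table
  under any test; the guarded t test returns p = 1 for identical constant
  groups and p = 0 for different constant ones. A raw-fluorescence mode
  inverts the quenching identities to emit Fs, Fm′, Fo′, Fm and relaxed-Fm′
  readings carrying the planted φPSII, qP, NPQ and qE (qE draws are clipped
  at NPQ, of which qE is a component).
* **Annotations.** Every term annotates genes at a baseline probability;
  planted (module, term, odds) triples multiply the annotation *odds* inside
  the module, so odds 1 is the null and odds infinity saturates the module.

All output is a deterministic function of the spec, including its seed
(Mersenne-Twister with inversion sampling, fixed explicitly); the generator
restores the caller's RNG state.

What passing simulations do **not** show: the generator has no
gene-length/GC structure, no count-level (negative-binomial) noise, no
correlated background, no batch effects, and its physiology noise is
homoscedastic Gaussian. Recovery on it validates the pipeline's logic, not
the upstream statistics of any particular sequencing workflow.

## Problem sizes and numerical choices

The bundled checks run the full pipeline on 2000-gene simulations (six
samples), where partition recovery, pattern recovery, planted-enrichment and
trait-attribution checks complete in seconds; statistical primitives are
verified against independent oracles (brute-force hypergeometric tails up to
N = 200, a step-up BH re-implementation, eigendecomposition for eigengenes,
textbook Welch formulas, 10^4 random readings for the quenching identity at
1e-12). Percentages in composition tables round half away from zero, the
convention of printed summaries, with exact fractions kept alongside.
Degenerate inputs are errors, not coercions: zero-variance genes must be
filtered before network construction, constant trait vectors yield NA
correlations rather than zero, and readers reject malformed tables with the
offending row or column named.

## Known limitations

* With two replicates per stage the internal DE path has limited power and
  its q-values are a stand-in; supply external statistics for publication
  analyses.
* The unsigned network cannot distinguish up- from down-regulated modules
  with mirrored profiles; use the TOM/signed extensions if that matters.
* Meta-module labels and module numbers are stable only for identical input.
* The eigengene-trait correlation treats stage-mean physiology replicated to
  transcriptome samples (n = 6 pairs by default) because the two assays used
  different individuals; with three stages these correlations have four
  degrees of freedom and are descriptive, not confirmatory. A stage-mean
  pairing (n = 3) is available by flag.
* R1 physiology has no transcriptome counterpart and is excluded from the
  correlation; this pairing is a declared convention.
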