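---
title: "knocknet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{knocknet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knocknet)
```

`knocknet` analyzes two-group knockdown expression experiments: negative
control (NC) versus shRNA knockdown (KD), a handful of arrays per group.
This vignette documents the statistical models behind each stage, the
parameters that matter and their defaults, what the synthetic-data
generator does and does not emulate, and the design choices made where the
design was genuinely open.

## Preprocessing model

Probe-level linear intensities are processed as floor → quantile
normalization → log2 → median-polish summarization (`rma_lite()`), the
robust multi-array average recipe with one deliberate substitution: the
convolution background-correction model is replaced by a configurable
intensity floor (`floor`, default 1.0 on the linear scale). The background
model's parameters are instrument-specific and cannot be estimated from
summarized data; a floor preserves the only property downstream steps rely
on (strict positivity before the log), and with synthetic data the
generator produces no background component to remove.

Quantile normalization maps each column onto the across-column mean of
order statistics. Ties within a column receive the mean of the reference
values their positions span (the average-rank dialect, matching
`limma::normalizeQuantiles(ties = TRUE)`, which the test suite uses as an
independent cross-check). Consequences asserted in tests: all columns share
one sorted vector afterwards, column sums are equal, within-column ranks
are preserved, and the map is idempotent.

Summarization fits the additive model
$y_{ij} = \mu + \alpha_i + \beta_j + \varepsilon_{ij}$ (probe $i$, sample
$j$) per probe set by Tukey median polish (`stats::medpolish` behind the
module surface) and reports $\hat\mu + \hat\beta_j$ as the gene-level
log2 value. Convergence uses the relative change in total absolute
residual, tolerance `1e-6`, capped at 10 iterations; hitting the cap is a
stopping rule, not an error. Single-probe genes pass through unchanged. An
independently coded sweep oracle in the tests reproduces the estimates to
1e-9.

## DEG screen

Per gene, a two-sample t-test on log2 values compares KD to NC, two-sided.
The default is the **pooled-variance Student test** (`var_equal = TRUE`).
At $n = 3$ per group this is a deliberate choice: Welch's
Satterthwaite-approximated degrees of freedom are estimated from two
variances with two degrees of freedom each, and the resulting null
p-values are visibly non-uniform at this sample size — enough to fail a
Kolmogorov–Smirnov uniformity check on a few thousand genes — whereas the
pooled test is exact under the generator's equal-variance normal model.
Welch remains one flag away (`var_equal = FALSE`) for data with suspected
heteroscedasticity. Degenerate genes (zero variance in both groups) get
$p = 1$ when the means agree and $p = 0$ otherwise.

Multiplicity is handled by Benjamini–Hochberg adjustment across all genes
(`bh_adjust()`, a validated wrapper over `stats::p.adjust`). "Corrected p"
is read as BH FDR throughout the package. A gene is called iff

$$\mathrm{FC} > 2 \ \text{or}\ \mathrm{FC} < 1/2, \qquad
  \text{and} \qquad p_{\mathrm{adj}} < 0.05,$$

with **strict** inequalities on both cuts: a gene at FC exactly 2.0 or
adjusted p exactly 0.05 is not called. Fold change is computed as
$2^{\overline{\mathrm{KD}} - \overline{\mathrm{NC}}}$ on the log2 scale,
consistent with the RMA-scale analysis.

## Directional enrichment

Enrichment is over-representation analysis: for a term with $K$ members in
the background of $N$ genes and a DEG list of size $n$ hitting $k$ of
them, the two-sided Fisher exact p sums hypergeometric point probabilities
not exceeding that of the observed table, with a relative tie tolerance of
$10^{-7}$ (the same tie dialect as `stats::fisher.test`, which serves as a
cross-check in the tests; an exhaustive enumeration over every consistent
table with $N \le 60$ agrees to $10^{-12}$). The Pearson $\chi^2$ (1 df,
no continuity correction) is reported as a companion statistic; where an
expected cell is zero it is recorded as missing. Fisher drives every
significance call — the two statistics are never arbitrated.

Design choices:

* **Background universe** = all genes present on the array after
  summarization, not the genome; this is the standard correction for
  array content and is fully configurable.
* **Directional runs**: enrichment is computed separately for up- and
  down-regulated DEGs (plus a combined run); a term significant in both
  directional runs is styled `up_down`, otherwise `up` or `down`. BH
  adjustment is applied within each run's term family.
* **−LgP** is $-\log_{10}$ of the *raw* p (it feeds histogram axes);
  significance always uses the adjusted p.
* Terms with no background members are dropped with a warning rather than
  silently scored.

## Networks and hub ranking

`parse_kgml()` reads the KGML dialect subset: `entry` elements (`id`,
`name` with one or more ids, `type` ∈ {gene, map}) and `relation` elements
(`entry1`, `entry2`, `subtype`). A relation between gene entries expands to
the full cross product of their id lists, directed entry1 → entry2, typed
by subtype (unknown subtypes map to `other` with a warning). A relation
touching a `map` entry becomes a single pathway-level `maplink`; a gene
entry on one side stands for the document's own pathway.

Both graphs use the same edge semantics, chosen because published hub
tables count *neighbor* pathways/genes, not parallel relations:

* edges are **deduplicated ordered pairs** — parallel relations merge,
  with their types kept as a multiset;
* **self-loops are dropped** (degree footnotes describe up-/down-stream
  partners, which a self-loop is not);
* outdegree = distinct downstream neighbors, indegree = distinct upstream
  neighbors, degree = outdegree + indegree.

The pathway-net takes the union of the up- and down-run significant
pathway sets as its node set (so all three styles can appear); an edge
requires both endpoints significant. The signal-net keeps called DEGs with
at least one qualifying edge. `rank_hubs()` sorts by degree descending,
ties by outdegree descending then id ascending — a deterministic total
order; published tables do not disclose their tie rule, so this one is
asserted only where degrees differ. Pathway-level crosstalk is taken from
KGML `maplink` relations, the only machine-readable pathway–pathway link
the dialect offers.

`pathway_deg_overlay()` is the tabular stand-in for coloring DEGs on a
pathway map: per pathway, the up- and down-regulated member lists and
their counts.

## qPCR and QC math

$\Delta Ct = Ct_{\text{target}} - Ct_{\text{reference}}$ per condition,
$\Delta\Delta Ct = \Delta Ct_{KD} - \Delta Ct_{NC}$, relative expression
$2^{-\Delta\Delta Ct}$. Replicate Ct values are averaged arithmetically
before differencing (standard practice; amplification-efficiency
correction is out of scope). Knockdown efficiency is
$100(1 - \mathrm{rel})$ percent. RNA quality gates are strict: A260/A280
> 1.9, concentration > 300 ng/µL, 28S/18S > 1.4 — a sample exactly at a
boundary fails, and improving any metric can never flip a pass into a
fail. Concordance between array and qPCR is the fraction of shared genes
whose fold changes lie on the same side of 1.

## The synthetic generator

`simulate_study()` emulates the two-group knockdown design with known
ground truth. Per gene, a baseline log2 intensity is drawn uniformly on
[4, 14] (the working range of expression arrays, spanning low and high
expressors without heavy tails). A planted fraction of genes
(`frac_deg`, default 0.02) is shifted by ±`effect_log2fc` (default 2) in
the KD group, split 50/50 up/down by default — symmetry is the neutral
choice, and an `up_fraction` knob emulates asymmetric responses such as
175 up / 365 down. Each probe carries a fixed offset
$\sim N(0, 0.5^2)$ so median polish has real work to do, and every
probe × sample cell gets i.i.d. $N(0, \texttt{noise\_sd}^2)$ noise
(default sd 0.25 on the log2 scale, a mid-range value for replicate
arrays). Annotation sets over-sample one DEG direction for planted
enriched terms (at least half of each enriched set's members); relation
documents are well-formed KGML-subset XML whose complete edge list is
recorded in the truth bundle; the qPCR table encodes one fewer
amplification cycle per planted log2FC unit in KD.

Each artifact type draws from its own RNG stream derived from the master
seed by a fixed offset, so enlarging the annotation never perturbs the
expression draws; a fixed configuration is byte-reproducible end to end.

What the generator does **not** emulate: scanner/optical noise and probe
sequence (GC) effects, background signal, probe-level outliers,
correlation between genes, annotation version drift, and the long-tailed
variance heterogeneity of real arrays. Recovery results on synthetic data
therefore demonstrate that the pipeline's statistics are calibrated and
its plumbing is correct under its stated model — not that real-data error
rates will match. In particular the equal-variance normal noise is exactly
the regime in which the pooled t-test is optimal; on real arrays a
moderated-variance test would be the stronger choice, and is deliberately
out of scope here.

## Problem sizes and numerical choices

The test suite and the acceptance script exercise the study design point
at 5000 genes × 4 probes × 3 + 3 arrays (the recovery and null-control
analyses; a single run takes a few seconds), exhaustive Fisher validation
over all ~6.4 × 10⁵ consistent 2×2 tables with $N \le 60$, 1000
random-vector BH comparisons, and random graphs up to 200 nodes — sizes
chosen so the full suite completes in about a minute while still crossing
every code path at realistic scale. Other numerical settings: median
polish tolerance `1e-6` / 10 iterations; Fisher tie tolerance `1e-7`
relative; quantile ties averaged; hub ties broken deterministically as
above. Degenerate inputs (empty DEG lists, terms outside the background,
relation documents without relations, isolated nodes) are all defined
rather than errors, and covered by tests.

## Known limitations

* No moderated-variance (empirical-Bayes) test; at $n = 3$ per group a
  limma-style shrinkage test would gain power on real data.
* No GO-graph topology: terms are flat gene sets; ancestry propagation is
  out of scope.
* No CEL-file ingestion or background deconvolution; input starts at a
  probe-level intensity table.
* Pathway crosstalk is limited to what maplink relations encode; curated
  pathway-interaction databases are richer.
* The χ² companion is reported but never arbitrated against Fisher.
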