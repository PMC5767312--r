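---
title: "Methods: priming-oriented expression analysis for two-genotype stress designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: priming-oriented expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtprime)
```

## The design and the question

`droughtprime` analyses replicated single-channel expression data from a
2 genotypes (tolerant vs sensitive) × 2 organs (leaf, root) ×
2 conditions (control, drought) design. Beyond the usual catalogue of
drought-responsive genes, it asks a sharper question: which genes does the
tolerant genotype hold, already under control conditions, at the
expression level the sensitive genotype reaches only after drought? Such
"stressed-like readiness" — constitutive priming — is a candidate
mechanism for tolerance, because a genotype that is already positioned for
stress does not need to mount a large transcriptional response when stress
arrives.

## Statistical model and contrasts

Within each organ the data form a balanced 2 × 2 (genotype × condition)
layout with $n$ replicates per cell (default 3). Per probe we fit the
cell-means parameterisation: the four cell means are arithmetic means of
log2 intensities, and the error variance is pooled within-cell variance
with $\nu = N_\text{organ} - 4$ degrees of freedom. A contrast between two
cells is tested with

$$t = \frac{\Delta}{\sqrt{\mathrm{MSE}\,(1/n_1 + 1/n_2)}},\qquad
  p = 2\,P(T_\nu \ge |t|),$$

and fold change is the geometric-mean ratio $\mathrm{FC} = 2^{|\Delta|}$.
Three contrasts are run per organ: drought vs control within each
genotype, and tolerant vs sensitive within control. BH adjustment is
applied across all probes separately per contrast; this matches treating
each comparison's probe list as its own discovery family. A probe is
called at $q \le 0.05$ with FC ≥ 3 for drought contrasts and FC ≥ 2 for
the initial (between-genotype, control) contrast — the lowered stringency
reflects the premise that even modest constitutive differences can be
useful head starts. Both gates are inclusive at the boundary.

Probes with zero pooled variance take the degenerate rule $p = 1$ when
$\Delta = 0$ and $p = 0$ otherwise, so noiseless fixtures remain fully
testable rather than being dropped.

This is deliberately the simplest model consistent with a two-factor
analysis and the comparisons actually reported downstream. We fit per
organ rather than one three-factor model: organs have largely distinct
transcriptomes here, a shared error term across organs would be
implausible, and every downstream question is posed within an organ.
No empirical-Bayes variance moderation is applied; the replicate structure
is honest in the simulator, and moderation would complicate the
zero-variance contract without changing any design decision downstream.

## Probe→gene collapse

The platform maps many probes to one gene (never one probe to many genes;
that is rejected as a mapping error). A gene passes in a direction iff at
least one mapped probe passes in that direction; genes with probes passing
in both directions carry a `conflict` flag, count in both direction
tallies, and are excluded from priming calls by default. The reported
gene-level statistics come from the representative probe — the passing
probe with the smallest q.

## The priming rule

For each organ, a gene is a priming candidate iff:

1. it shows an initial difference: FC ≥ 2, q ≤ 0.05 in the
   tolerant-vs-sensitive control contrast, signed by which genotype is
   higher;
2. it passes the sensitive genotype's drought contrast (FC ≥ 3,
   q ≤ 0.05);
3. the directions agree: tolerant-higher with sensitive drought-up
   (`primed_high`), or tolerant-lower with sensitive drought-down
   (`primed_low`) — the sensitive genotype moves under drought toward the
   level the tolerant genotype already holds.

Note what the rule does **not** require: absence of a drought response in
the tolerant genotype. "Responding in the sensitive genotype" is read as a
requirement on the sensitive genotype only, not as exclusivity — a
substantial fraction of genuine candidates are also (more weakly)
drought-responsive in the tolerant genotype, and excluding them would
discard exactly the genes where readiness and response coexist. The
overlap is therefore recorded per call (`tolerant_drought_overlap`) and
summarised per organ class, but never used as a filter. A stricter
exclusivity reading can be emulated downstream by filtering on the flag.

Candidates are classified across organs (root_only / leaf_only / both,
with a discordance flag when the two organs' directions differ), and the
selection is monotone in its thresholds: raising either fold-change floor
or lowering α never adds a call.

## GO enrichment

Enrichment is singular enrichment analysis: the input list (by default the
priming candidates) against an annotated background, one upper-tail
hypergeometric test per term,

$$p = \sum_{k=x}^{\min(n,K)} \frac{\binom{K}{k}\binom{N-K}{n-k}}{\binom{N}{n}},$$

computed via the stable distribution function (`phyper`). Direct
annotations are first propagated to all ancestors over the is_a/part_of
DAG (true-path rule; the DAG is checked acyclic). A term is significant at
raw p ≤ 0.01 with at least 5 mapped input genes; raw p is the default
because the SEA convention this mirrors reports unadjusted values, and an
optional BH switch is provided. Genes without any annotation are excluded
from both $N$ and $n$. The ontology reader is a deliberately minimal OBO
parser (id / name / namespace / is_a / part_of; obsolete terms skipped).

## Sample clustering

Samples are clustered on the full normalized probe matrix with Euclidean
distances and Ward's linkage in the squared-Euclidean dialect (`ward.D2`:
squared distances inside the Lance–Williams update, heights reported on
the distance scale), which guarantees monotone merge heights. Tie-breaking
among exactly equal merge criteria follows the `hclust` implementation;
on continuous expression data exact ties have probability zero, so the
choice is not observable in practice. Whole-transcriptome clustering (not
DEG-restricted) is used, matching the convention of presenting the global
sample structure.

## Normalization

Per chip, the 75th percentile (linear interpolation between closest
ranks, $r = 1 + q(n-1)$ — R's default quantile convention, fixed so
results are bit-stable) is subtracted from each sample column; afterwards
that percentile is exactly zero in every column, and any additive
per-array offset (multiplicative on the linear scale) is removed exactly.
Then each probe row is centred on its median across **all** samples —
both organs, both genotypes, both conditions — which preserves cross-organ
comparability of a probe's profile. The order is fixed as: drop probes
with missing intensities, log2-transform with a floor of 1, percentile
shift, baseline. Contrast estimates are invariant to everything these
steps remove.

## qPCR validation stack

* **Efficiency**: per well, the mean fluorescence of cycles 1–5 is
  subtracted as a fixed baseline; log10 of the corrected signal is
  regressed on cycle over every contiguous window (default 5 cycles)
  inside the strictly increasing region, and the window with maximal
  $R^2$ gives $E = 10^{\text{slope}}$. Per amplicon, estimates from wells
  with $R^2 \ge 0.99$ are averaged. This is a window-of-linearity
  simplification: the full iterative baseline search of dedicated tools
  is out of scope, and on clean exponential curves the fixed baseline
  recovers the generating base to well under 0.001.
* **Ratio**: $R = E_t^{\Delta Ct_t} / E_r^{\Delta Ct_r}$ with
  $\Delta Ct = \overline{Ct}_\text{control} - \overline{Ct}_\text{treated}$;
  at $E = 2$ on both sides this is the classical $2^{\Delta\Delta Ct}$ to
  machine precision.
* **Significance**: fixed-reallocation randomization on
  $|\log R^\ast|$; when all $\binom{n_1+n_2}{n_1}$ label reallocations
  number at most 10 000 they are enumerated exhaustively (p is then the
  exact fraction at least as extreme, identity included); otherwise 2000
  random reallocations with the add-one estimator
  $(1 + \#\text{extreme})/(1 + n_\text{perm})$.
* **Concordance**: Spearman rank correlation (average ranks on ties)
  between array and qPCR log2 fold changes, permutation p, seeded.
* **Display value**: $40 - (Ct_\text{target} - Ct_\text{reference})$, a
  convention placing target = reference at 40 with one unit per cycle.

## The synthetic-data generator

Every stage is exercised on simulated data with planted truth. The
generator emulates the study design: 2 × 2 × 2 × 3 samples, 2000 genes,
1–3 probes per gene sharing the gene's true cell means plus per-probe
constant offsets and independent Gaussian log2 noise (SD 0.5), per-array
additive log2 offsets (SD 0.3) that the percentile shift removes exactly,
and 50 unmapped control probes.

Planted structure, all magnitudes drawn as floor + Exponential excess
(heavy-tailed fold changes, as on real arrays):

* **Drought DEGs**: 25 genes per (genotype-exclusivity × organ class ×
  direction) cell, response floor 2.0 log2 (FC 4) with mean excess 1.5.
* **Priming candidates**: 20 primed-high and 20 primed-low per organ
  class; initial difference floor 1.5 log2 (FC ≈ 2.8, mean excess 1.25)
  held by the tolerant genotype in both conditions, sensitive drought
  response floor 2.0; 30% also receive a same-direction tolerant drought
  response, exercising the overlap bookkeeping.
* **Plain initial differences**: 100 genes per organ class differing
  between genotypes without any drought response — ordinary genotype
  divergence, and the natural false-positive challenge for the priming
  selector.
* **Background factor structure**: per-gene random coefficients with SDs
  3 (organ) > 0.25 (condition) > 0.15 (genotype). The organ term
  dominates everything else, reproducing the organ-first sample
  dendrogram; the condition and genotype terms sit far below the
  fold-change floors so background genes do not crowd the labelling
  boundary.

Ground-truth labels are a pure function of the true cell means and the
fold-change floors (`truth_from_means()`), so stored labels can always be
reproduced by recomputation, and a background gene whose random
coefficient genuinely crossed a floor would be labelled a true positive.

Choices of the planted set sizes and spreads were made once, from a
design-stage power calculation at the study conditions (noise 0.5, n = 3,
pooled df 8): with ≈280 true genes per contrast and the stated floors,
gene-level sensitivity of the joint priming rule is expected near 0.93,
comfortably above the 0.9 recovery property the test suite asserts, while
the false discovery proportion stays below 0.05.

What the generator does **not** emulate: scanner and spatial artifacts,
dye chemistry, probe×condition interactions, correlated noise between
probes of a gene, or unbalanced designs. Passing tests therefore
demonstrate the pipeline's correctness under its own model assumptions —
Gaussian log2 noise and additive array effects — not robustness to
real-array pathologies upstream of the intensity matrix.

One property of the default truth is worth noting: because
genotype-exclusive drought responses are planted as genuinely absent in
the other genotype, the two genotypes' drought samples are legitimately
far apart, and the k = 4 cut of the default dataset's dendrogram need not
be organ × condition. The organ × condition split is asserted on
configurations where the three factor effects carry the structure
(e.g. SDs 3 / 1 / 0.3 with no planted exclusivity), which is the regime
that property describes.

## Numerical and degenerate-input conventions

* Quantile convention: type 7 ($r = 1 + q(n-1)$), fixed for bit-stable
  tests.
* Zero-MSE probes: the degenerate p rule above, not dropping.
* BH on an empty vector returns an empty vector; m = 1 returns p.
* Hypergeometric counts are validated (`0 ≤ x ≤ min(n, K)`, `K, n ≤ N`)
  before testing; x = 0 short-circuits to p = 1.
* Efficiency estimates are clamped to (1, 2.5] with a warning outside
  (1, 2.1]; curves with no strictly increasing above-baseline window of
  the requested size are estimation errors, not silent skips.
* All stochastic operations take an explicit integer seed; one seed
  regenerates a dataset bit-identically.

## Problem sizes used by the test suite

The default simulated design is 2000 genes (≈4000 probes) × 24 samples;
recovery properties average 10 such datasets, BH null calibration uses
20 replicates of a 1000-gene global-null design, the enrichment null uses
50 annotation draws, and exhaustive oracles run at their natural small
sizes (all hypergeometric configurations to N = 12, all C(6,3)
reallocations, trees to 6 leaves). These sizes give stable Monte-Carlo
estimates for every asserted property while keeping the full suite in the
low minutes.

## Known limitations

* The ANOVA is per organ with a pooled within-cell variance; no variance
  moderation or probe-quality weighting.
* Enrichment p values depend on the supplied background; with a different
  annotation release the same input list yields different p values, so
  only count identities and planted-truth recovery — not literature
  p values — are meaningful checks.
* The efficiency estimator assumes a visible exponential phase; very late
  or saturated curves fail fast rather than extrapolating.
* No GEO/series-matrix downloader is bundled; the readers accept plain
  exported TSV matrices, and no result here depends on network access.
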