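# droughtprime

Priming-oriented differential expression analysis for two-genotype stress
transcriptomes.

## The problem

When a stress-tolerant and a stress-sensitive genotype are profiled across
two organs (leaf, root) and two watering conditions (control, drought), an
interesting class of genes emerges: genes the tolerant genotype already
expresses at a "stressed-like" level under normal water supply, which the
sensitive genotype only reaches after drought sets in. Such constitutive
readiness is a candidate mechanism of stress tolerance. `droughtprime`
implements the full analysis that identifies these priming candidates from
single-channel expression arrays, together with every surrounding stage:
normalization, contrast testing, DEG partitioning, GO enrichment, sample
clustering, and qPCR cross-validation — plus a synthetic-data generator
with planted ground truth so the whole pipeline is testable end to end.

## The method

For a probes × samples log2 intensity matrix over the
2 genotypes × 2 organs × 2 conditions × *n* replicates design:

1. **Normalization** — per-chip percentile shift to the 75th percentile
   (linear-interpolation order statistic), then a baseline transformation
   to the median of all samples. Both remove additive per-array and
   per-probe offsets exactly.
2. **Differential expression** — per organ, a 2 × 2 cell-means fit per
   probe with pooled error variance (df = N − 4); contrasts are tested
   with *t* = Δ / √(MSE(1/n₁ + 1/n₂)); p values are BH-adjusted across
   all probes per contrast. A probe is differential when q ≤ 0.05 and
   FC = 2^|Δ| ≥ 3 (drought vs control within a genotype) or FC ≥ 2
   (tolerant vs sensitive under control — the lowered stringency for
   initial differences). Probes collapse to genes via a many-to-one
   probe→gene map: a gene passes in a direction iff some mapped probe
   does.
3. **DEG partitioning** — per organ into tolerant-only / sensitive-only /
   shared, and across organs into root-exclusive / leaf-exclusive / both;
   class counts always sum to the universe total.
4. **Priming selection** — a gene is a priming candidate in an organ iff
   it has an initial between-genotype difference (FC ≥ 2, q ≤ 0.05),
   passes the sensitive genotype's drought contrast (FC ≥ 3, q ≤ 0.05),
   and the directions agree: tolerant-higher with sensitive drought-up
   (`primed_high`) or the mirror (`primed_low`). Overlap with the tolerant
   genotype's drought DEGs is recorded, never used as an exclusion.
5. **GO enrichment** — singular enrichment analysis: true-path propagation
   over an is_a/part_of DAG, upper-tail hypergeometric p per term,
   significant at p ≤ 0.01 with at least 5 mapped input genes.
6. **Clustering** — Euclidean distances between samples, Ward linkage
   (`ward.D2`), Newick export.
7. **qPCR validation** — window-of-linearity amplification-efficiency
   estimation, the efficiency-corrected ratio
   R = E_target^ΔCt(target) / E_ref^ΔCt(ref), fixed-reallocation
   randomization significance, (40 − dCt) relative expression, and
   Spearman concordance between array and qPCR log2 fold changes.

## Worked example

```r
library(droughtprime)

ds  <- simulate_dataset(sim_config(seed = 7))       # planted-truth dataset
rep <- run_pipeline(ds$raw, ds$samples, ds$probe_map)
sc  <- score_against_truth(rep, ds$truth)

sc$priming
#> $sensitivity
#> [1] 0.918239
#> $fdp
#> [1] 0.03947368
#> $n_true
#> [1] 159
#> $n_called
#> [1] 152

head(rep$priming[, c("gene_id", "organ", "priming_direction", "organ_class")])
#>   gene_id organ priming_direction organ_class
#> 1  G00328  root        primed_low   root_only
#> 2  G00451  root       primed_high   root_only
#> 3  G00452  root       primed_high   root_only
#> 4  G00453  root       primed_high   root_only
#> 5  G00454  root       primed_high   root_only
#> 6  G00456  root       primed_high   root_only

table(rep$priming$organ_class[!duplicated(rep$priming$gene_id)])
#>      both leaf_only root_only
#>        35        42        40
```

Of the 159 planted (gene, organ) priming labels in this dataset, the
pipeline recovers 92% with a 4% false-discovery proportion; the calls
table carries per-gene fold changes, q values, organ class
(root_only / leaf_only / both) and the tolerant-genotype overlap flag.
`run_pipeline_files()` is the file-based front end (TSV in, TSV/JSON/Newick
out, with a checksummed manifest).

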