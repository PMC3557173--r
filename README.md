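# cottonmap

Diagnostics for dense genetic linkage maps of allotetraploid cotton and
integration of those maps with physical sequence resources.

## The problem

Interspecific BC1 populations (e.g. (TM-1 × Hai7124) × TM-1) yield
dense linkage maps — thousands of SSR, REMAP, SNP and InDel loci on 26
linkage groups spanning the At and Dt subgenomes. Turning such a map
into a genomic resource requires a chain of analyses that this package
implements for R users working on cotton (or any comparable
allopolyploid mapping design):

* **Segregation diagnostics.** Each BC1 individual is recurrent-parent
  homozygous (coded 1) or heterozygous (coded 3); Mendelian
  transmission predicts 1:1. Per locus, the Pearson chi-square
  statistic is

  χ² = (n₁ − n₃)² / (n₁ + n₃),  df = 1,

  with no continuity correction. Loci with P < α (default 0.05) are
  skewed toward the recurrent parent (n₁ > n₃) or the heterozygote
  (n₃ > n₁), and maximal runs of ≥ 3 consecutive same-direction
  distorted loci form segregation distortion regions (SDRs), named
  `SDR<k>_<chromosome>` in map order.

* **Map structure.** Locus density in 10-cM bins; clusters of ≥ 5 loci
  per sliding 1-cM window, classified as gene islands (≥ 5 EST-SSR loci
  in a window) or retrotransposon-rich regions (REMAP majority);
  duplicated-locus accounting for multi-locus markers, classifying each
  duplicated locus as homoeologous (Ai ↔ Di bridge), same-chromosome,
  or different non-homoeologous, with reciprocal-translocation signals
  for declared candidate pairs (A2/A3, A4/A5).

* **In silico PCR anchoring.** Primer pairs are screened against
  EST/BAC pools under a Hamming bound (mismatch ≤ 3) with the
  convergent forward–reverse (FR) match pattern required for a product.
  The search is exact via the pigeonhole principle: a primer split into
  `max_mismatch + 1` segments must match one segment exactly, so exact
  segment lookup plus full verification finds every site a naive scan
  finds. An X-drop seed-and-extend matcher (`seed_extend()`) handles
  arbitrary queries against long BAC templates. Cross-species product
  sizes are compared to flag insertion/deletion variation.

* **QTL integration.** Anchored markers become per-marker clusters with
  a greedy-merged representative unigene; fiber-quality QTL (FL, FS,
  FF, FE, FU) whose intervals are within 20 cM are mined for clusters
  mapping inside them, with a per-chromosome summary table and
  single-linkage QTL clustering.

* **Synthetic data.** Seeded generators emit every input — map,
  BC1 genotypes, primers, FASTA pools, QTL and duplication tables —
  with a ground-truth manifest, so every detector is scored exactly.

## Worked example

A small end-to-end run on synthetic data (seed 42; four linkage groups
A1/A2/D1/D2 of 60 loci, one planted distortion region, 30 primer pairs
with 60% planted amplicons):

```r
library(cottonmap)
cfg <- sim_config(seed = 42, n_groups = 4, loci_per_group = 60,
                  distortion_regions = data.frame(group = "A1", start_cM = 40,
                                                  end_cM = 55, p3 = 0.70),
                  amplicon_plan = list(n_markers = 30, frac_success = 0.6,
                                       n_decoys = 5, n_bac = 1,
                                       template_len = 300))
gm <- generate_map(cfg)
summarize_map(gm$map)
#> 240 loci in 4 linkage groups covering 551.01 cM
#> mean inter-locus distance: 2.33 cM; mean loci/group: 60

bc <- generate_bc1(gm$map, cfg)
res <- classify_loci(bc$genotypes)
scan_sdrs(gm$map, res)[, 1:6]
#>     name group           direction start_cM end_cM n_loci
#> 1 SDR1_1    A1 toward_heterozygote    40.84  54.34      7
```

The planted region (transmission probability 0.70 for the heterozygote
class over 40–55 cM on A1) is recovered as a single SDR of 7 loci
skewed toward the heterozygote; 25 of 240 loci are distorted overall —
the planted run plus the expected ~5% false positives at α = 0.05.

```r
sq <- generate_sequences(cfg)
anchors <- anchor_pool(sq$primers, sq$pool)
anchors
#> 18/30 primer pairs (60.0%) amplified products from 36 ESTs and 1 BACs
```

Anchoring recovers exactly the 18/30 planted markers (60.0%), each from
its two species copies. Integrating with generated QTL:

```r
qt <- generate_qtl(gm$map, cfg)
m2l <- data.frame(marker = sq$primers$marker,
                  locus = gm$map$locus[seq(1, 240, by = 8)])
cl <- build_clusters(anchors, gm$map, m2l)
intg <- integrate_qtl(qt$qtls, gm$map, cl)
intg
#> 14 QTL retained (2 excluded by interval width), 2 ESTs/genes assigned
tail(intg$summary, 3)
#>    chromosome qFE qFL qFF qFS qFU qtl_total n_genes
#> 5 At_subtotal   3   0   2   0   1         6       1
#> 6 Dt_subtotal   1   1   3   1   2         8       1
#> 7       Total   4   1   5   1   3        14       2
```

Two generated QTL are wider than the 20-cM rule and are excluded; the
per-chromosome table carries At/Dt subtotals that always sum to the
grand total. `run_pipeline()` chains all stages over files on disk and
writes `map_summary.json`, `distortion.tsv`, `sdrs.tsv`,
`clusters.tsv`, `duplication.json`, `anchors.gff3`, `integration.tsv`,
`table2.tsv`, `unigenes.fasta` and a parameter-logging `run.log` under
a run directory; `inst/cli/linkmap.R` exposes the same stages as shell
subcommands.

See `vignettes/map-integration.Rmd` for the full account of the models,
parameter choices and limitations.

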