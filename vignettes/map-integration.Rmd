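---
title: "Linkage-map diagnostics and sequence anchoring with cottonmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage-map diagnostics and sequence anchoring with cottonmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cottonmap)
```

## The analysis

Dense genetic linkage maps of allotetraploid cotton (*Gossypium
hirsutum* x *G. barbadense* interspecific crosses) are built from a BC1
backcross population: each individual at each marker locus is either
homozygous for the recurrent parent (coded 1) or heterozygous (coded 3),
with Mendelian transmission predicting a 1:1 ratio. cottonmap implements
the downstream analyses such a map supports:

1. **Map summaries** — locus counts, lengths, mean inter-locus spacing
   and residual gaps.
2. **Segregation diagnostics** — per-locus chi-square tests against 1:1,
   classification of the skew direction, and scanning for segregation
   distortion regions (SDRs).
3. **Map structure** — locus-density binning, cluster / gene-island /
   retrotransposon-region calling, and duplicated-locus analysis across
   the homoeologous At/Dt subgenomes, including reciprocal-translocation
   signals.
4. **Sequence anchoring** — an in silico PCR engine that screens SSR
   primer pairs against EST/BAC sequence pools, plus an ungapped
   seed-and-extend matcher for long templates.
5. **Integration** — representative-unigene selection for anchored
   clusters and co-localization of anchored genes with fiber-quality QTL
   by genetic-distance windows.

A seeded synthetic-data layer generates every input with planted ground
truth, so all detectors are scored exactly.

## Statistical and algorithmic choices

### Mean inter-locus spacing

`summarize_map()` divides the total map length by the number of
adjacent-locus *intervals*, `n_loci - n_groups` (a group of n loci has
n − 1 intervals). Published cotton map reports mix two conventions —
dividing by intervals for the whole map but by loci for subgenome
figures; we standardize on intervals throughout, so a subgenome mean
computed here can differ from a published per-locus figure in the second
decimal. Means are rounded half-away-from-zero to two decimals
(`round_half_up()`), matching how such tables are printed; base R's
round-half-even would disagree on exact ties.

### Chi-square segregation testing

`chi_square_1to1()` is the Pearson statistic with expectation
`(n1 + n3)/2` per class and one degree of freedom, with **no** Yates
continuity correction: at n = 138 the correction is negligible and the
uncorrected statistic matches the convention in mapping studies.
Missing calls are dropped per locus, never imputed. The significance
level defaults to 0.05 **uncorrected** across loci — distortion scans in
the mapping literature report per-locus P < 0.05, and an SDR is defined
by spatial coherence rather than familywise error control. A tie
n1 = n3 yields chi-square 0, so a "distorted tie" cannot occur and no
tie-break rule is needed.

### SDR definition

The field describes SDRs qualitatively as clustered same-direction
distorted loci. We operationalize: a maximal run of at least `min_run`
(default 3) consecutive map-order loci, all significant and all skewed
the same way. Three is the smallest run that is not a pair; it is a
parameter, not a claim. SDRs are numbered globally in map order and
named `SDR<k>_<chromosome>`, with cotton linkage-group labels translated
to conventional chromosome numbers (A1–A13 are chromosomes 1–13; the
D-subgenome follows the cytogenetic assignment D1 = 15, D2 = 14,
D3 = 17, ...; other labels fall back to their embedded digits).

At the default study conditions — n = 138, heterozygote transmission
probability 0.70 inside a planted region — the per-locus expected
chi-square is about 22, so individual loci are flagged with probability
above 0.99 and a 5-locus region is recovered essentially always; the
test suite asserts ≥ 99/100 seeded replicates. Under fair transmission
the per-locus false-positive rate is the nominal 5% (the binomial
discreteness at n = 138 gives ≈ 0.0498), and same-direction triples are
rare enough that spurious SDRs appear in well under 5% of 131-locus
groups.

### Density bins and clusters

`bin_density()` uses half-open bins `[kw, (k+1)w)` of width 10 cM, with
the last bin closed so the locus at the group maximum is counted exactly
once. `detect_clusters()` operationalizes "≥ 5 loci/cM" as at least
`min_loci` loci inside a sliding window of `window` cM over the sorted
positions; overlapping qualifying windows are merged into one maximal
cluster. Merging can in principle chain dense runs into a cluster whose
total span slightly exceeds one window — every member still lies in some
qualifying sub-window, which is what the density phrase asserts. A
cluster is a *gene island* when at least five EST-derived (eSSR) loci
fall within one window span inside it, and *retrotransposon-rich* when
REMAP loci make up strictly more than half its members (the observed
exemplar is 8 of 15); both thresholds are parameters.

### Duplicated loci and translocation signals

A marker mapping to m ≥ 2 loci contributes m duplicated loci. Each
duplicated locus is classified by where the marker's *other* loci lie:
*homoeologous* if the partner group (A_i ↔ D_i, shared index) is hit,
else *same chromosome*, else *different non-homoeologous* — an
exhaustive, disjoint partition at the locus level. Reciprocal
translocations between A-subgenome chromosomes (Ai, Aj) leave a
signature of markers bridging Ai with Dj and Aj with Di;
`detect_translocation_signals()` counts such marker-level bridges for
user-declared candidate pairs (defaults A2/A3 and A4/A5, the documented
cotton rearrangements).

### In silico PCR

`match_primer_sites()` finds every end-to-end placement of a primer on
either template strand with at most `max_mismatch` substitutions
(default 3). Matching is pure Hamming — no indels inside a primer site,
and no special 3'-terminal penalty: the screen is a sequence-identity
filter, not a thermodynamic model. Template Ns count as mismatches;
primers must be unambiguous A/C/G/T.

Search is exact by the pigeonhole principle: the primer is split into
`max_mismatch + 1` contiguous near-equal segments, and any placement
within the bound must match at least one segment exactly. Exact segment
hits are located by a C-level fixed-string scan over the template pool
concatenated with `N` separators (an exact A/C/G/T segment can never
straddle a separator), and every candidate offset is verified by a
vectorized full comparison. This is provably equivalent to the naive
scan of every offset and strand; the test suite asserts equality on
hundreds of random primer/template combinations.

`find_amplicons()` requires the convergent FR pattern: the forward
primer on one strand and the reverse primer on the opposite strand
downstream, product size measured 5' end to 5' end inclusive, within
`[min_product, max_product]`. Defaults are 40 bp minimum and 5,000 bp
(EST) / 20,000 bp (BAC) maximum — the source screen names no bounds, so
they are configuration, sized to what EST inserts and BAC products can
physically support. All placements are reported, since multi-locus
markers genuinely amplify several products. Coordinates are 1-based
inclusive throughout (the R/Biostrings idiom), and the GFF3 writer
emits them unchanged.

`seed_extend()` provides the long-template route: exact k-mer seeds
(default k = 12) shared by query and template (either strand) are
extended ungapped in both directions under X-drop termination (+1
match, −2 mismatch, X-drop 12, minimum reported score 30 — a standard
ungapped-extension parameterization, all exposed). Overlapping matches
on one diagonal collapse to the best-scoring one.

### Unigene selection

"Longest possible unigene" is implemented as greedy exact-overlap
merging: repeatedly merge the pair of member sequences with the longest
suffix/prefix overlap of at least 40 bp at ≥ 95% identity (left
sequence wins inside the overlap), then take the longest resulting
sequence. This is deliberately not an overlap-layout-consensus
assembler; the `provenance` field records whether the representative
was merged or is simply the longest member, and the result is never
shorter than the longest member.

### QTL integration

QTL whose flanking-marker interval exceeds 20 cM are excluded before
mining — the published rule filters on the interval itself, which we
adopt; intervals are closed in cM on the named group. A cluster is
assigned to a QTL if *any* of its mapped positions falls inside, and
each (QTL, cluster) pair counts once. The summary table mirrors the
conventional per-chromosome layout (QTL counts by the five fiber traits
FL/FS/FF/FE/FU, assigned-gene counts, At/Dt subtotals, grand total).
`cluster_qtl()` replaces meta-analysis software with single-linkage
grouping of overlapping same-chromosome intervals — a deliberate
simplification that captures multi-trait QTL clusters without a mixture
model.

## The synthetic-data layer

The generators emulate the study design, not cotton biology: 26 groups
(A1–A13, D1–D13) of 131 loci over 141 cM with marker types drawn at the
frequencies of a dense cotton map; 138 BC1 individuals with independent
per-individual transmission at probability p3 (0.5 fair, region
overrides for planted SDRs) and 1% missing calls (no published rate; a
realistic genotyping default); uniform-composition templates of 600 bp
(ESTs) and 10 kb (BACs) with amplicons planted at recorded offsets,
0–3 planted primer substitutions, and +6 bp insertions in a 63.9%
fraction of second-species copies; a duplication plan realizing the
multiplicity histogram {2: 287, 3: 37, 4: 2} with 181 homoeologous-pair,
40 same-group and 66 cross-group duplicated markers, 37 triplicated and
2 tetraplicated — which reproduces the published marginals (693 loci
from 326 markers, 64.07% homoeolog bridging) by construction.

One master seed feeds independent per-module streams, so adding a
generator never perturbs another's draws and identical configurations
are byte-identical. What the simulations do **not** model: linkage
between loci (genotypes are independent across loci, so SDR spatial
structure comes only from planted regions), recombination-based map
construction, repeat structure or SSR motifs in templates, and
sequencing error. Passing tests therefore demonstrate the correctness
of the *detectors* under the stated statistical model, not robustness
to the full messiness of real genotyping and GenBank data.

Test and script problem sizes are deliberately desk-scale: anchoring
runs at 1,000 markers against ~1,380 templates, calibration at 10,000
loci x 138 individuals, recovery at 100 seeded replicates — large
enough for the binomial and pigeonhole arguments to bind, small enough
to re-run routinely.

## Degenerate inputs and numerical corners

* All-singleton groups make the inter-locus mean undefined; this is an
  error, not NA.
* An all-missing locus is untestable and raises an error naming the
  locus.
* Gap detection is strictly greater-than (a spacing exactly at the
  threshold is not a gap); cluster spans use a 1e-9 tolerance so
  positions printed at 2 decimals compare as intended.
* Primers shorter than `max_mismatch + 1` cannot be pigeonhole-split
  and are rejected.
* `min_product > max_product` and non-positive bin widths are parameter
  errors.
* Percentages print to 2 decimals (shares) or 1 decimal (anchoring
  success), rounded half-away-from-zero.

## Known limitations

The package anchors by primer sites only; it does not evaluate primer
thermodynamics, allow gapped primer alignments, or compute BLAST-style
E-values. Unigene merging requires near-exact overlaps and will leave
chimeric or low-identity overlaps unmerged by design. QTL clustering is
interval overlap, not a statistical meta-analysis. Centromere inference
from density peaks is out of scope — peaks are reported, not
interpreted.
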