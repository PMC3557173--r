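Package: cottonmap
Title: Genetic-Map Diagnostics and In Silico PCR Anchoring for Allotetraploid Cotton
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing dense genetic linkage maps and integrating
    them with physical sequence resources, built around the interspecific
    BC1 mapping design used in allotetraploid cotton. Provides chi-square
    1:1 segregation testing and segregation-distortion-region scanning,
    locus-density binning with cluster and gene-island calling, duplicated
    locus (multi-locus marker) accounting across homoeologous At/Dt
    chromosomes, a mismatch-bounded in silico PCR engine that anchors SSR
    primer pairs to EST and BAC sequence pools, greedy unigene selection,
    and QTL-gene co-localization by genetic-distance windows. Seeded
    synthetic-data generators emit every pipeline input together with a
    ground-truth manifest for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
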