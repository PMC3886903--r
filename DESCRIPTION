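Package: chemevolve
Title: Analysis of Experimental Evolution in Nitrogen-Limited Chemostats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing microbial experimental-evolution studies in
    continuous culture: a genotype-tree Wright-Fisher simulator of adapting
    asexual populations with Sanger- and deep-sequencing-like observation
    models, selection-coefficient estimation from pairwise competition assays,
    allele-frequency trajectory clustering and nested genotype (Muller plot)
    reconstruction, combinatorial fitness-landscape and epistasis analysis with
    accessible-path enumeration, pooled-population variant-filtering heuristics
    and mutation-spectrum statistics, and gene-set expression-divergence and
    functional-enrichment tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
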