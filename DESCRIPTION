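Package: sarnet
Title: Shade-Avoidance QTL Mapping and Candidate-Gene Network Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci (QTL) for phenotypic
    plasticity in recombinant inbred line (RIL) populations and for
    prioritizing candidate genes under a QTL by fusing co-expression,
    expression-QTL (eQTL), functional-annotation and polymorphism evidence.
    Implements sun/shade condition indices with nuisance-factor adjustment,
    subtraction and residual shade-avoidance response indices with a
    Shapiro-Wilk normality gate, Haley-Knott interval mapping with
    permutation-based genome-wide LOD thresholds and 2-LOD support
    intervals, informative line-subset selection, mutual-rank co-expression
    neighborhoods, eQTL colocalization filtering with the
    contiguous-marker-interval confidence rule, GO-Slim functional
    coherence coloring, and hub ranking of candidate regulators. A fully
    seeded synthetic-data generator (Haldane map, selfed-RIL genotypes,
    genotype-by-environment phenotypes, latent-factor expression
    compendium, annotation/eQTL/polymorphism layers with planted ground
    truth) makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    rtracklayer
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
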