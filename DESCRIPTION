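Package: digenicBSR
Title: Digenic Recessive Trait Mapping by Bulked Segregant RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for mapping a trait controlled by
    two unlinked recessive nuclear genes, modelled on a Brassica rapa leaf-colour
    (chlorophyll-deficient) mutant study design. Provides a forward breeding
    simulator (reciprocal F1, F2, BC1, F2:3 and F3:4 generations with Poisson
    crossover meiosis), Mendelian segregation-ratio tests with Yates continuity
    correction and exact digenic expectations by gamete enumeration, the
    Euclidean-distance (ED^5) bulked-segregant statistic with top-quantile
    thresholding and candidate-region calling, recessive-class linkage analysis
    with the Kosambi mapping function and flanking-marker interval delimitation,
    and RPKM-based differential-expression screening intersected with mapped
    intervals to nominate candidate genes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'digenicBSR-package.R'
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'genome.R'
    'breeding.R'
    'bulks.R'
    'segregation.R'
    'bsr.R'
    'linkage.R'
    'expression.R'
    'io.R'
    'pipeline.R'
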