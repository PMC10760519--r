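Package: TrioDNM
Title: Trio-Based Germline De Novo Mutation Calling, Phasing and Spectrum Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection and characterisation of germline de novo single-base
    mutations (DNMs) from trio sequencing evidence. Implements a posterior-based
    candidate caller with an ordered hard-filter cascade (depth, allele balance,
    strand support, region masks, population frequency, parental evidence and a
    binomial allele-balance test with FDR correction), read-backed
    parent-of-origin phasing with the paternal:maternal alpha statistic,
    96-channel trinucleotide mutation spectra with cross-genome signature
    catalog renormalisation and nonnegative exposure refitting, Poisson
    regression models of mutation burden with parental age and genotype
    covariates, callable-genome depth quantisation and per-generation mutation
    rate estimation, and screens for candidate causal genotypes. A synthetic
    trio cohort generator reproduces the statistical structure of control and
    maternal-hypermutator pedigrees, including the sequencing artifact classes
    each filter stage is designed to remove, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    pracma,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: VariantDetection, Genetics, Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
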