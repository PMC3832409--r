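Package: RRLpanel
Title: Reduced-Representation SNP Panel Design, Filtering and Relatedness
    Inference
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing reduced-representation libraries (RRL) by
    in-silico restriction digestion, filtering putative SNPs from
    consensus-stack catalogs through a multi-criterion cascade, computing
    SNP-panel statistics (minor allele frequency, heterozygosity, exact
    Hardy-Weinberg tests, D' linkage disequilibrium, X-linkage detection),
    selecting marker panels, and inferring pairwise relatedness with the
    Lynch-Ritland estimator including parent-offspring exclusion by
    autosomal allele sharing and X-chromosome inheritance. Seeded synthetic
    generators produce genomes, pedigree genotype panels and stack fixtures
    with ground truth so the whole pipeline runs without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
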