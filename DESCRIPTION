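Package: pulseekR
Title: Prediction and Quantitation of Polysaccharide Utilization Loci in
    Marine Bacteroidetes Metagenomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting polysaccharide utilization loci (PULs) in
    Bacteroidetes metagenome-assembled genomes (MAGs) and relating them to
    approximate-species clusters, substrate classes and abundance. Implements
    two-tier filtering of CAZyme, sulfatase and SusC/SusD annotation evidence
    (HMMER domain hits confirmed by DIAMOND-style similarity hits), gap-based
    locus extraction with susC/susD and degradative-CAZyme retention rules,
    rule-based substrate classification of called loci, MinHash (Mash)
    sketching and distance for approximate-species clustering of MAGs with
    quality gates and representative selection, greedy 95 percent-identity
    dereplication of SusC/SusD genes with taxonomy voting, RPKM and
    percent-NSAF quantitation, and a synthetic-data generator that plants
    loci, genome pairs at known divergence, read counts and spectral counts
    with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Metagenomics, Microbiome, Annotation, Clustering, Proteomics
RoxygenNote: 7.3.3
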