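Package: ddgbs
Title: Design and Evaluation Toolkit for Double-Digest Genotyping by
    Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for planning and evaluating double-digest
    genotyping-by-sequencing (ddGBS) experiments: in silico single- and
    double-enzyme restriction digestion of reference genomes with
    fragment end-labelling and size selection; barcode design and
    exact-match demultiplexing; enzyme-combination scoring statistics
    (fragment consistency index, per-fragment sequencing depth and its
    coefficient of variation, SNP density uniformity, region summaries);
    read-subsampling saturation curves with optimal and saturated
    read-count points for sequencing-volume planning; depth-stratified
    genotype quality control, chip concordance and linkage-disequilibrium
    decay; and a ddGBS read simulator with planted SNPs and truth
    genotypes so every analysis can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
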