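Package: trdscan
Title: Transmission Ratio Distortion and Genetic Incompatibility Scans in
    Advanced Intercross Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects transmission ratio distortion (TRD) in two-founder
    advanced intercross lines from trio genotype data.  Implements trio-based
    pedigree quality control, Hardy-Weinberg exact gating, chi-square
    transmission-asymmetry tests on alleles transmitted by heterozygous
    parents, LOD-based region calling, pairwise Bateson-Dobzhansky-Muller
    incompatibility scans between TRD regions with simpleM effective-test
    correction, permutation tests for nonsynonymous-SNP enrichment, generic
    hypergeometric set overrepresentation, and a protein-protein interaction
    overlay on incompatible region pairs.  A forward-in-time pedigree
    simulator with Haldane recombination, injectable meiotic drive and
    two-locus viability selection generates fully synthetic inputs with known
    ground truth so every stage of the pipeline can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
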