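Package: crossimpute
Title: Reference-Free Genotype Imputation and Design Exploration for F2
    Crosses of Inbred Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates multi-parent F2 crosses of inbred lines sequenced at
    low coverage, imputes genotypes without a reference panel by alternating
    a diploid Li-Stephens haplotype-copying hidden Markov model with
    expectation-maximization updates of a set of ancestral haplotypes, and
    evaluates the result against held-out high-coverage truth samples.
    Includes the iterative SNP-set refinement loop, per-sample and minor
    allele frequency binned concordance metrics, depth/sample/cross
    downsampling procedures, a sequencing cost model, and a cost-versus-
    accuracy sweep for planning cross designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
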