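Package: xyypair
Title: Sex-Chromosome Pairing Analysis for XYY Drosophila Males
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing "competitive" sex-chromosome pairing in
    XYY Drosophila melanogaster males under the 2+1 pairing model, in
    which two of the three sex chromosomes (X, Y1, Y2) pair and disjoin
    while the third segregates at random. Provides the probabilistic
    pairing model (configurations L, M, N; six sperm classes; viability
    weighting), a method-of-moments estimator of pairing-configuration
    frequencies with vial-bootstrap intervals, summaries of vial-structured
    progeny counts, Welch-posterior intervals for differences of class
    frequencies across replicate and transfer-time subsets, two-sample
    required-sample-size calculations, regression of class frequency on
    rDNA copy number, delta-delta-Ct relative rDNA copy-number
    quantification from replicate qPCR cycle thresholds, and synthetic
    generators for vial counts, control crosses and qPCR replicates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
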