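Package: surfbat
Title: Surrogate-Family-Based Association Testing from Imputation Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-only, local-ancestry-robust association testing in the spirit
    of the transmission-disequilibrium test. Each case haplotype is modelled as
    a mosaic of a phased reference panel under a Li-Stephens copying hidden
    Markov model; the copying posteriors yield an imputed ("transmitted") allele
    dosage and a "pseudo-control" dosage built from the partner haplotypes of
    the copied reference individuals. Paired (conditional-likelihood TDT) and
    unpaired (marginal homogeneity) chi-squared tests are computed per variant,
    together with INFO and minor-allele-frequency filters, genomic inflation
    and genomic control. Includes panel merging with Hudson's Fst outlier
    exclusion, genetic-map handling, and a mosaic-haplotype simulator for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
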