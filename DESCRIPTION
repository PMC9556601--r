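Package: butterflycall
Title: Within-Sample SNP Genotype Calling from Two-Channel Bead-Array
    Intensities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genotype calling for Illumina Infinium-style SNP bead arrays
    from per-SNP two-channel signal intensities, using a within-sample
    three-component bivariate normal mixture (the "butterfly" geometry of
    the AA/AB/BB clusters in log-intensity space) fitted by
    expectation-maximisation with unconstrained component covariances.
    Calls are made by maximum a posteriori probability with tunable
    no-call rules (posterior threshold, minimum bead count,
    zero-intensity dropouts). Includes probe-manifest filtering and A/B
    allele to plus-strand base translation, assembly of per-SNP
    intensities from address-level colour-channel records, a calibrated
    synthetic-data simulator with ground-truth genotypes, and
    concordance evaluation against reference (e.g. whole-genome
    sequencing) call sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
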