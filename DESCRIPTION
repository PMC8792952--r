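Package: herddiv
Title: Pedigree and SNP-Based Genetic Diversity Analysis for Livestock Herds
Version: 0.1.0
Authors@R:
    person("herddiv", "maintainers", email = "maintainers@herddiv.org",
           role = c("aut", "cre"))
Description: Tools to quantify genetic diversity in managed livestock
    populations from pedigree and medium-density SNP data. Implements
    pedigree inbreeding (tabular kinship method), complete generation
    equivalents, generation intervals by selection pathway, SNP quality
    control, consecutive-runs detection of runs of homozygosity (ROH) and
    the genomic inbreeding coefficient F_ROH, effective population size
    from pedigree inbreeding trends and from linkage-disequilibrium decay,
    and segmented regression statistics for comparing inbreeding rates
    between breeding-program eras. Includes forward simulators (pedigree
    gene dropping with known autozygosity, Wright-Fisher populations of
    known effective size) so every estimator can be validated against
    ground truth, plus a command-line driver for end-to-end analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
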