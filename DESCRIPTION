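Package: sparsekin
Title: Kinship, Sex and Mitochondrial Genome Inference from Sparse
    Degraded-DNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the low-coverage shotgun-sequencing analyses used on
    highly degraded samples such as aged rootless hair shafts. Implements
    forced pseudo-haploid relatedness inference from sparse SNP data with a
    Monte Carlo null over relationship classes and genotyping error rates,
    biological sexing from length-normalised X-to-autosome read ratios (Rx),
    and circular mitochondrial genome analysis via a chimeric doubled
    reference with origin liftover, duplicate removal, consensus calling with
    point-heteroplasmy handling, and haplotype difference reporting. A
    synthetic-data layer emulates degraded shotgun libraries (sparse
    correlated coverage, genotyping error, terminal cytosine deamination,
    origin-spanning fragments) so every stage is testable without access to
    restricted samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
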