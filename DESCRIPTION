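Package: ogri
Title: Taxonogenomic Species Delineation with Genome Relatedness Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delineating new bacterial species by the
    taxonogenomic approach: 16S rRNA identity screening against the
    98.65%/95% species and genus thresholds, Kimura 2-parameter distances
    with partial-deletion site filtering, neighbor-joining trees with
    nonparametric bootstrap supports, reciprocal-best-hit orthology under
    identity and coverage floors, the AGIOS, AAI and digital DNA-DNA
    hybridization genome relatedness indices, and the threshold-based
    species verdict. Includes a forward simulator of annotated genome
    pairs diverged under the Kimura 2-parameter model with known ground
    truth, so that every estimator in the pipeline can be checked by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
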