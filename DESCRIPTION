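Package: ricepanel
Title: Design and Deployment Analysis of Fixed Rice SNP Genotyping Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing fixed single-nucleotide-polymorphism (SNP)
    genotyping panels from a re-sequenced diversity panel and for analysing
    the data such panels produce in rice genetics and breeding. Panel design
    applies flanking-variant and repeat filters to a dense candidate catalog,
    qualifies markers by within-subpopulation allele frequency and by
    segregation in target biparental crosses, and selects a fixed panel under
    per-megabase spacing guarantees and per-subpopulation quotas. Deployment
    analyses cover pairwise polymorphism scoring, neighbor-joining trees with
    locus bootstrap, principal component analysis, parent-relative graphical
    genotypes, introgression-segment delimiting, marker-assisted backcross
    background selection, and chromosome segment substitution line (CSSL)
    library evaluation. A seeded simulator generates structured diversity
    panels, dense variant catalogs, and backcross/CSSL populations with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
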