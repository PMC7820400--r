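Package: strpopgen
Title: Forensic STR Population Genetics and Structure Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic analysis of autosomal short tandem repeat
    (STR) profiles as used in forensic frequency surveys: per-locus forensic
    summary statistics (heterozygosity, polymorphic information content,
    match probability, power of exclusion, paternity index) and their
    multi-locus combinations, Hardy-Weinberg and linkage-disequilibrium
    permutation testing, bracketed repeat-structure nomenclature parsing and
    off-ladder allele designation, Nei DA genetic distances with
    neighbour-joining trees and principal component ordination, an
    admixture-model Gibbs sampler with Evanno delta-K model selection, and a
    Balding-Nichols genotype simulator for calibration. Ships the published
    23-locus Kuwaiti PowerPlex Fusion 6C allele-frequency table as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
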