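Package: fivexp
Title: Analysis of 5'-Tagged (5'XP) Small RNA Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for 5'XP small RNA sequencing, a library strategy that
    ligates an 11-nt oligonucleotide tag to 5'-phosphorylated RNA so that
    phosphorylation-sensitive (5P-tag) and insensitive (5X-notag)
    sub-libraries can be separated bioinformatically. Implements native read
    preprocessing (two-color-chemistry quality trimming, 3' adapter removal
    with minimum overlap, whole-read quality filtering, 5'-tag splitting),
    unique-sequence counting with abundance filters and counts-per-million
    normalization, hierarchical mismatch-tiered annotation against small RNA
    biotype references, terminal and loop classification of tRNA- and
    rRNA-derived fragments from secondary-structure files, per-reference
    coverage profiles, and descriptive analytics including size
    distributions, first-nucleotide bias, fold differences, correlation
    clustering and saturation-curve regression. A seeded simulator generates
    tagged and untagged reads with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
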