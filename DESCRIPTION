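Package: mitohet
Title: Mitochondrial Heteroplasmy Detection, Haplotype Phasing and
    Recombination Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising mitochondrial heteroplasmy and
    recombination in haploid (fungal) population samples. Implements a
    double-peak heterozygous base caller for Sanger-style trace peak
    profiles with a windowed noise floor, replicate confirmation and
    singleton audits; expectation-maximisation phasing of heteroplasmic
    sequences against homoplasmic reference isolates with classification
    of each haplotype mixture as locally explainable, globally
    explainable or unexplained; relative per-cell mitochondrial copy
    number estimation from quantitative PCR threshold cycles against a
    two-copy nuclear reference; and multilocus clonality and
    recombination inference via the index of association, rbarD,
    within-locus allele-shuffling permutation nulls, pairwise
    phylogenetic compatibility (generalised four-gamete test) and clone
    correction. A seeded synthetic-data generator produces genotype
    matrices, heteroplasmic mixtures, trace profiles and Ct panels with
    the statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
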