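Package: exsitu
Title: Ex Situ Conservation Assessment of Allelic Diversity in Living
    Collections
Version: 0.1.0
Authors@R:
    person("Plainsboro", "Genetics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to score how well botanic-garden (ex situ) collections
    represent the allelic diversity of wild (in situ) populations from
    co-dominant diploid genotype data. Reads Genepop, STRUCTURE and VCF
    files; applies missing-data (R0/R80) and first-variant-per-locus
    filters; stratifies wild alleles into frequency categories (very
    common, common, low frequency, rare) and reports the percentage of
    each category captured in garden samples; estimates by resampling the
    minimum number of wild individuals needed to cover 95% of total wild
    allelic diversity, with an exact hypergeometric oracle; computes
    expected heterozygosity, rarefied allelic richness and Nei mean
    pairwise FST among wild populations; and simulates structured
    metapopulations (Balding-Nichols model), garden collections,
    missingness and de novo error alleles so every stage is testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
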