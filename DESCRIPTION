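Package: ohnodiverge
Title: Regulatory Divergence of Whole-Genome-Duplication Ohnologue Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies salmonid Ss4R ohnologue pairs from rooted gene trees
    and duplicated-block synteny, classifies rediploidization timing from
    windowed sequence similarity, and quantifies regulatory divergence between
    duplicated clock genes: tissue expression divergence index (EDI),
    nonparametric rank-correlation rhythm screening against cosine reference
    waveforms with a permutation null, negative-binomial differential
    expression for developmental time courses and salinity challenges, nested
    sixth-order polynomial profile comparison by extra-sum-of-squares F test,
    and Pearson-correlation profile clustering. A seeded synthetic-data
    generator with recorded ground truth makes the full pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    edgeR,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
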