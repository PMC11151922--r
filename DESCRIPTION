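Package: pollistab
Title: Partitioning Temporal Invariability of Plant-Pollinator Metacommunities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical partitioning of the temporal invariability (1/CV) of
    plant-pollinator metacommunity variables -- floral availability, pollinator
    visitation rates, plant-pollinator interaction frequencies and fruit set --
    across organizational levels (population, community, region), together with
    the species- and spatial-synchrony indices that link the levels, Taylor's
    power-law mean-variance scaling, and a synthetic two-trophic metacommunity
    generator with known ground-truth synchrony and scaling for end-to-end
    testing of the pipeline without field data. Survey data enter as tidy
    long-format tables and every result is returned as a tibble.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
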