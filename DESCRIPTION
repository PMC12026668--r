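Package: discrimindex
Title: Country-Level Discrimination Index from Differentiated Policy Stringency Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a daily, country-level discrimination index as the
    difference between composite pandemic-response policy indices (the
    Containment and Health Index or the Stringency Index) evaluated
    separately for non-vaccinated and vaccinated population groups, from
    OxCGRT-style wide daily policy panels. Provides the indicator codebook,
    readers for the OxCGRT version-1 national dialect and a
    countries-by-continent lookup, the flag-adjusted sub-index and
    composite-index engine, year stacking, per-country summaries and
    rankings, zero-discrimination partitions, regional groupings,
    ordinary-least-squares associations, equal-interval classification for
    choropleth export, timeline tables, and a deterministic synthetic-panel
    generator with a closed-form oracle for end-to-end parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
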