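Package: polliflow
Title: Pollen Flow, Paternity and Spatial Genetic Structure in Mapped
    Plant Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of codominant (microsatellite) genotypes from mapped,
    open-pollinated plant populations: genetic diversity and fixation-index
    permutation tests, Loiselle pairwise coancestry with distance-class
    correlograms and the Sp statistic, group coancestry and variance effective
    population size, categorical-likelihood paternity assignment with
    simulation-derived Delta critical values and pollen-flow summaries, and
    maximum-likelihood fitting of an exponential-power pollen dispersal kernel
    under a spatially explicit neighborhood mating model. Includes a
    synthetic-population simulator with full parentage ground truth for method
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
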