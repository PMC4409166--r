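Package: ecoevopart
Title: Partitioning Eco-Evolutionary Change in Microbial Community Productivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing serial-transfer experiments on assembled
    microbial communities: growth-curve yields and generation counts, random
    partitioned community designs, additive (sum-of-monoculture) expectations
    and interaction indices, and a counterfactual regression framework that
    partitions change in community yield over time into ecological sorting
    (species extinction), additive evolution of species yields, and evolution
    of species interactions. Includes a fully parameterised simulator of such
    experiments with switchable generating mechanisms, so every inference
    stage can be validated by parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
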