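Package: assaychoice
Title: Cost-Effective Assay Choice for Rare-Disease Study Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision support for choosing among genetic assays (genotyping
    chips, exome sequencing, genome sequencing) when designing or extending
    rare-disease gene-discovery studies on a fixed budget. Models the chance
    that a case's complete disease-causing mechanism is observed as v^c,
    where v is the assay hit rate and c the disease complexity (number of
    jointly required risk mutations); the number of completely observed
    mechanisms across n cases is then binomial with mean n v^c. Provides
    assay ranking by cost-effectiveness v^c / P, breakeven analysis for
    extending a study with new subjects versus re-assaying existing ones,
    partitioning of the price-ratio / hit-rate-ratio parameter space by
    favoured strategy, and a Monte-Carlo simulator of the generative model
    as an independent check on the closed forms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
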