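Package: nocimap
Title: Mapping Inflammatory Mediators to Visceral Nociceptor Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native re-implementation of the computational chain used
    to nominate secreted inflammatory mediators as activators of visceral
    nociceptors, from bulk transcriptomics of inflamed gut biopsies to the
    physiology that validates a candidate. Provides negative-binomial
    differential expression with TMM normalization and an exact conditional
    test; Fisher-exact gene-set enrichment with rank z-scores and combined
    scores; mediator-to-receptor prioritization against single-neuron
    expression matrices; Ca2+ imaging trace normalization and responder
    classification; extracellular afferent spike detection and peak firing-rate
    change quantification; minimum-error thresholding and watershed-based cell
    counting; assumption-gated group comparisons; and a synthetic-data module
    that generates every input kind with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    png,
    withr
Config/testthat/edition: 3
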