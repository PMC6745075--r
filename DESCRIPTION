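Package: aquarisk
Title: Human Health Risk Assessment for Metals in Drinking Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for US-EPA-style human health risk
    assessment of arsenic and toxic heavy metals (Hg, Pb, Cr, Ni) in drinking
    water. Reads station-level concentration tables with non-detect handling,
    computes average daily doses through ingestion and dermal contact for
    adult and child receptors, derives target hazard quotients, hazard
    indices, and incremental lifetime cancer risks with threshold
    classification, compares concentrations against WHO/EPA/Iranian
    guidelines, and ships a seeded lognormal generator for synthetic
    monitoring campaigns. Includes a 35-station urban distribution-network
    survey as a packaged example dataset together with calibrated parameter
    bundles that reproduce its published dose and hazard tables.
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
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
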