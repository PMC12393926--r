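Package: aquatrial
Title: Analysis of Aquaculture Feeding Trials with Inert-Marker
    Digestibility, Nutrient Mass Balance and Molecular Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for tank-based fish feeding trials:
    apparent digestibility coefficients by the inert-marker (yttrium
    oxide) ratio method, growth and feed-utilisation indicators (weight
    gain, SGR, FCR, PER, somatic indices), daily phosphorus mass balance
    and nutrient retention on a digestible-intake basis, thermal growth
    coefficient (TGC) projection and feeding-plan generation, diet
    global-warming-potential aggregation from per-ingredient factors,
    Pfaffl efficiency-corrected qPCR relative expression with multi-gene
    reference normalisation, and a statistical layer with
    variance-stabilising transforms, assumption-gated testing, planned
    contrasts and auto-scaled principal component analysis. A synthetic
    trial generator with embedded ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
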