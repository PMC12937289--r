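Package: feedval
Title: Feed Ingredient Energy and Ileal Amino Acid Digestibility Evaluation for Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for evaluating feed ingredients in
    growing-pig trials. Computes diet digestible and metabolizable energy
    from total-collection balance records, ingredient energy by the
    difference (substitution) method, apparent and standardized ileal amino
    acid digestibility from indigestible-marker (titanium dioxide) ratios
    with basal endogenous-loss correction, chemical-composition variability
    summaries, and chemical-composition-based prediction equations via
    best-subset and stepwise regression. Includes a synthetic trial
    generator for incomplete Latin-square designs so every estimation stage
    can be validated by parameter recovery, plus packaged reference tables
    from a ten-sample enzymolytic soybean meal evaluation study.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
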