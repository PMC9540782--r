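Package: lakech4
Title: Observation-Driven Upscaling of Global Lake Methane Emissions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Upscales lake methane (CH4) flux measurements to a daily,
    0.25-degree gridded emission climatology by pathway (diffusion,
    ebullition, ice-out/spring turnover, fall turnover). Implements
    compilation filtering and diel correction, exponential
    temperature-flux seasonality, ecoclimatic lake-type classification
    from permafrost/soil-carbon/soil-temperature layers, satellite-style
    freeze/thaw emission seasons, an accumulation-oxidation model for
    episodic fluxes, large-lake flux scaling, and quadrature propagation
    of six uncertainty components. A synthetic-data module generates all
    inputs with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
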