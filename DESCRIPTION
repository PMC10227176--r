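Package: hydrodisp
Title: Evolution of Hydrochorous Seed Dispersal in Fragmented Riverine Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators of seed-dispersal evolution for shoreline plants whose
    seeds are carried downstream by river flow (hydrochory). Provides a
    seed-size-dependent exponential dispersal kernel calibrated from median
    dispersal distances, a deterministic single-plant fitness-maximization
    model with hill-climbing evolution of seed size, a stochastic
    individual-based model on a periodic one-dimensional landscape, up-then-down
    inter-patch-distance sweep protocols that detect critical transitions and
    evolutionary hysteresis in dispersal capacity, and sensitivity-analysis
    grids over demographic and evolutionary parameters. Results are returned as
    tibbles and can be plotted with ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
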