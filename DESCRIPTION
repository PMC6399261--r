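Package: carbonfuse
Title: Model-Data Fusion for a Linear Multi-Pool Terrestrial Carbon-Cycle Emulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Emulates the carbon cycle of a process-based vegetation model as a
    linear system of pools (traceability framework): carbon influx is allocated
    to vegetation pools, transferred along a directed network of litter and soil
    pools, and leaves each pool at a baseline rate modified by an environmental
    scalar. Because the system is linear, simulated influx and apparent turnover
    rates can be replaced by estimates derived from observational datasets
    (model-data fusion), and the resulting aboveground biomass, soil carbon and
    net biome production compared against independent reference data with
    Willmott's index of agreement, Pearson correlation and RMSE, aggregated over
    land-cover classes and judged against the agreement between the reference
    datasets themselves (baseline knowledge). Includes a synthetic-data
    generator (gridded truth, biased model world, noisy pseudo-observations and
    a net-flux reference series) so the full analysis runs without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
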