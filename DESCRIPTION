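Package: deepclick
Title: Sperm Whale Click-Train Detection and Movement-Strategy Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying seasonal movement of deep-diving odontocetes
    through fixed passive acoustic monitoring. Implements a two-step
    click-train detector (band-limited energy detection followed by
    constant rounded inter-detection-interval run filtration), daily and
    monthly presence metrics with seasonal models and inter-click-interval
    demographics, an individual-based simulation of four candidate movement
    strategies observed through two acoustic listening ranges with
    root-mean-square-deviation model comparison, and extraction of the
    North Pacific Transition Zone latitude from gridded sea-surface
    temperature with ranged major axis regression. A synthetic-data module
    generates labeled hydrophone audio, reference presence series and SST
    grids so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    mgcv,
    car,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
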