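Package: migroutes
Title: Seasonal Ranges and Migration Routes from GPS Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing GPS telemetry of migratory ungulates:
    screening of raw relocation data (gross-outlier and movement-spike
    filters), rule-based segmentation of annual trajectories into winter,
    spring migration, calving, summer and fall migration, fixed-kernel
    utilization distributions with likelihood cross-validation bandwidth
    selection, Brownian bridge movement models for migration corridors,
    population-level route composites, and range-overlap and site-fidelity
    summaries. Includes a synthetic trajectory generator with known
    ground-truth season labels emulating an arctic caribou sampling design,
    so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
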