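Package: vlcost
Title: Micro-Costing of Centralized Viral Load Testing Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Activity-based costing of centralized HIV viral load testing
    networks in low-resource settings. Computes per-visit patient costs
    (transport, lodging, food, lost income) with catchment-weighted averages,
    per-specimen costs at specimen collection sites (supplies, labour,
    accommodations, amortized shipment), central-laboratory cost per specimen
    as a function of batch size under whole-kit reagent consumption with
    per-run controls, batch-size optimization, inverse inference of kit
    configuration from observed reagent costs, and attrition-adjusted cost
    per test result delivered to the clinic and to the patient. Includes a
    seeded synthetic network generator, YAML/CSV configuration loading with
    schema validation, and report table emission.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
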