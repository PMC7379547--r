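Package: cryoplan
Title: Optimal Collection and Cryogenic Storage Planning for Livestock Gene Banks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning the collection and cryogenic storage of livestock
    germplasm (semen doses) across a network of gene banks. Implements a capacitated
    facility-location model with semicontinuous per-breed storage levels, an exact
    structured solver (per-breed decomposition, transportation linear program and
    fixed-charge branch-and-bound), an independent cost engine for maintenance,
    collection-campaign and travel costs, named reallocation scenarios (baseline,
    unconstrained least cost, capacity-limited, single-bank centralization),
    budget-sweep diversity-cost curves, and a seeded synthetic breed-inventory
    generator calibrated to published per-bank and per-species dose totals by
    iterative proportional fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
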