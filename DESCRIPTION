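Package: forestvar
Title: Plot-Level Variation in Tree Mortality and Growth from Forest
    Inventory Remeasurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates plot-level random effects on tree mortality and
    diameter growth from paired forest-inventory censuses using a
    multivariate hierarchical Bayesian model, and propagates the fitted
    effect distributions through a cohort-based stand simulator in which
    demographic effects follow a stationary first-order vector
    autoregression.  Includes a synthetic inventory generator with known
    ground truth, disturbance-frequency summaries based on log-normal
    mortality multipliers, and simulation experiments contrasting chronic
    (background) versus episodic (disturbance) increases in mean mortality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
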