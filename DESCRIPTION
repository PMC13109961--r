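Package: reefevo
Title: Eco-Evolutionary Metacommunity Simulation of Coral Cover and Thermal Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates four competing coral assemblages (fast/slow growing,
    reef/nonreef) on a network of habitat sites under monthly temperature, pH
    and light forcing. Coral fractional cover grows through colony linear
    extension modulated by Gaussian thermal performance, linear pH response,
    saturating light response and linear competition, and declines through
    threshold-quadratic heat, cold and absolute-limit stress mortality. A
    single quantitative trait, the population-mean thermal optimum, evolves
    under stabilizing selection with cover-throttled response and is admixed
    by larval immigration. Annual spawning redistributes larvae through
    competency-weighted potential-connectivity kernels with free-space-limited
    settlement. Includes synthetic generators for climate-scenario forcing and
    dispersal kernels, a spin-up/scenario experiment driver with exact
    checkpoint-resume, and diagnostics for cover area, community composition
    and thermal disequilibrium.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
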