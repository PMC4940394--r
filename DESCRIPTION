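Package: dsdesign
Title: System Design Space Analysis of Biochemical Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Deconstructs intractable generalized mass action (GMA) and
    rational-rate-law models of biochemical systems into tractable dominant
    S-system phenotypes. Enumerates the phenotypic repertoire of a model by
    linear-programming feasibility over log-space polytopes, solves each
    dominant S-system analytically for steady states, logarithmic gains and
    local stability, measures global parameter tolerances, and predicts
    parameter sets that realize single phenotypes or ensembles of phenotypes
    (intersections, co-localizations and constrained arrangements). Includes
    tools for visualizing design-space slices, state-space trajectory
    classes, fixed points and basins of attraction, and for simulating the
    full model with transient stimulation events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    generics,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
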