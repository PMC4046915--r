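Package: oscimet
Title: Optimally Tuned Periodic Enzyme Forcing in a Kinetic Model of
    Escherichia coli Central Carbon Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an extended kinetic model of Escherichia coli central
    carbon metabolism (glycolysis, gluconeogenesis and the pentose phosphate
    pathway; 18 metabolites, 32 reactions) in which every reaction rate is
    scaled by a dimensionless enzyme level, and searches for time-periodic
    enzyme-level programs (cosine or square waves in amplitude, frequency and
    phase) that maximize the time integral of a target metabolite,
    phosphoenolpyruvate, over a finite horizon under metabolite path
    constraints. Includes step-test sensitivity screening of all enzymes,
    knockout and overexpression scenarios, time-invariant (constant-level)
    control optimizations, a coupled light-circuit style anti-phase program,
    Pearson correlation analysis of trajectories, a toy-network fixture
    generator with closed-form steady states, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
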