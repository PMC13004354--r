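Package: subflowr
Title: Flow Dynamics of Subretinal Injections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hydraulic and jet-flow modelling of subretinal injection systems
    used to deliver gene therapies. Computes Hagen-Poiseuille resistances of
    tubing segments in series, steady-state flow rates and tip exit velocities
    under machine, syringe-friction and ambient (intraocular) pressures, and the
    speed of the immersed dye jet leaving the cannula via a momentum-conserving
    1/z decay law whose constant is fitted to bench measurements. Summarises and
    fits post-injection residual-flow durations with a logarithmic
    pressure-duration model, compares priming and ambient-pressure conditions by
    one-way ANOVA, and recommends a post-injection pause before cannula
    withdrawal. Includes a synthetic bench-rig data generator for parameter
    recovery testing, packaged reference tables for common commercial cannulas,
    and a reporting pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
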