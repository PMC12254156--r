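Package: reaimsd
Title: System Dynamics Modelling of Reach, Maintenance and Implementation
    Cost in Public Health Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic stock-and-flow simulation of population engagement
    with a public health program, organised around the reach, implementation
    and maintenance domains of the RE-AIM framework. A five-compartment
    pathway (unaware, not engaged, not initially participating, participating,
    disengaged) is integrated with fixed-step difference equations; per-person
    activity-cost curves price the support strategies (initial and delayed
    reach, retention, re-engagement) and accumulate the cumulative cost of
    program delivery. A scenario engine sweeps initial reach and disengagement
    over a grid under four support-strategy presets and summarises the
    resulting participation and cost surfaces. Includes CSV/JSON writers,
    heatmap rendering and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
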