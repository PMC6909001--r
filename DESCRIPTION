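Package: fluxcom
Title: Community Genome-Scale Metabolic Modeling and Cross-Feeding Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of multi-species microbial communities
    built from member genome-scale metabolic models. Provides flux balance and
    flux variability analysis, model curation diagnostics (elemental and charge
    balance, thermodynamically infeasible cycle detection by null-space
    grouping, blocked and duplicate reactions), GapFind/GapFill mixed-integer
    programs for network gaps, a bilevel community formulation with a shared
    extracellular metabolite pool solved by KKT big-M reformulation, a
    gap-fill-driven workflow that classifies candidate fills into rejected
    fixes, accepted fixes, and de novo inter-species metabolite exchanges,
    augmentation of members with viral auxiliary metabolic gene reactions with
    flux-range shift reporting, and robustness analysis of flux ranges under
    alternative community objectives. Includes a synthetic community generator
    with planted, machine-readable ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    reticulate,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
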