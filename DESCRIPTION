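Package: plucksim
Title: Bio-Economic Simulation of Pluck-Lesion Impacts on Pig Farm Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the prevalence of pluck lesions observed at
    slaughter (pleurisy, enzootic pneumonia-like lesions, lung scars,
    abscesses, pericarditis, liver milk spots) relates to grower-finisher
    average daily gain and to whole-farm profitability in farrow-to-finish
    pig production. Provides a regression-tree engine with cost-complexity
    pruning and cross-validated tree-size selection to locate prevalence
    cut-offs; a synthetic farm-cohort generator for testing; a weekly
    steady-state herd-flow model with Gompertz growth and metabolic-weight
    feed demand; an itemized enterprise budget (profit and loss account);
    Monte Carlo risk analysis with modified-PERT inputs and Iman-Conover
    rank-correlation induction; and first- and second-order stochastic
    dominance comparison of profit distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    rpart,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
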