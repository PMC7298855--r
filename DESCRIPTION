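Package: dcelink
Title: Discrete Choice Experiment Analysis of Public Preferences for
    Linked Health Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing discrete
    choice experiments (DCEs) on public acceptability of research uses
    of anonymised linked administrative and health data.  Provides
    blocked main-effects choice-set designs with dominance filtering and
    D-efficiency diagnostics, synthetic respondent panels with
    demographic quotas and sequential route-out screening, random-utility
    choice simulation with an opt-out alternative, maximum-likelihood
    estimation of conditional logit models (per-country, pooled with
    nationality interactions, and heteroskedastic with a group scale
    parameter), and forecasting of scenario acceptance probabilities
    with attribute-level what-if analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
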