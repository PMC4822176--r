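Package: ppscct
Title: Bayesian Analysis of Peripersonal Space from Crossmodal Congruency Data
Version: 0.1.0
Authors@R:
    person("PPS", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for studying peripersonal-space (PPS) representation with the
    crossmodal congruency task (CCT): simulation of trial-level reaction-time
    experiments and ownership questionnaires, voice-onset reaction-time
    extraction from WAV recordings, computation of crossmodal congruency
    effects (CCE), hierarchical Bayesian linear and ordinal-logit hypothesis
    models, and posterior model probabilities via a transdimensional
    product-space (Carlin-Chib) Gibbs sampler with pseudo-prior fitting,
    Savage-Dickey oracles, and Monte-Carlo diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
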