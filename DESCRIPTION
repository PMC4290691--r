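Package: qualmc
Title: Qualitative Model Checking for Multi-Valued Signaling Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building discrete multi-valued logical models of
    signaling networks and verifying their temporal behaviour with
    computation tree logic (CTL) model checking.  Networks are updated by a
    clamped activator-minus-inhibitor transfer rule; transition systems can
    be built under synchronous (simultaneous) or asynchronous (interleaved,
    one process per step) semantics, the latter with process fairness
    constraints.  Verification runs on a reduced ordered binary decision
    diagram (BDD) backend implemented in C++, with a brute-force
    explicit-state checker serving as an independent oracle on small
    systems.  Ships a reconstructed 30-node ER-Golgi stress network
    together with a suite of disease- and oscillation-related CTL
    properties and a reproduction harness for their expected verdicts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
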