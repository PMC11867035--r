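Package: dappmap
Title: Viable Dynamic Adaptive Policy Pathway Maps for Coupled
    Infrastructure Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Dynamic Adaptive Policy Pathway (DAPP) maps for
    social-ecological systems represented as Ostrom-style coupled
    infrastructure system (CIS) compartment models.  Provides the CIS
    action-rate dynamics for a resource and three social roles
    (exploitation, conservation, policy-making), nested governance
    arrangements encoded as role/link masks with operational intensity
    ranges, finite-horizon viability kernels under ecosystem-service
    constraints computed with a backward grid algorithm, enumeration and
    scoring of governance pathways as epoch-layered directed graphs, and a
    retrospective sensitivity analysis of ecosystem-service security gains.
    Ships a fully synthetic hedgerow/ecosystem-services case generator
    (five hedgerow composition classes, seven services and disservices,
    rural and peri-urban constraint sets, three climate stress levels) so
    the whole pipeline runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
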