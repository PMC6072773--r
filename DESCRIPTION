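Package: aaqsp
Title: Whole-Body PBPK/PD Simulation of COX-2 and 5-LOX Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A quantitative systems pharmacology pipeline coupling reduced
    whole-body physiologically based pharmacokinetic (PBPK) models of
    anti-inflammatory drugs (celecoxib, diclofenac, licofelone, zileuton)
    and rifampicin with a cellular ODE network of arachidonic-acid
    metabolism.  Unbound drug concentrations drive competitive inhibition
    of COX-2 and 5-LOX, suppressing prostaglandin E2 and omega-LTB4
    formation; efficacy is summarised by a drug efficacy score against a
    paired drug-free control.  Rifampicin-mediated PXR activation of CYP
    enzymes is modelled as a turnover cascade and fed back into the PBPK
    layer to study pharmacokinetic drug-drug interactions and dose
    adjustment.  Includes a Hill-model correlation layer for linking
    predicted PGE2 decrease to clinical pain-relief scores, SBML
    import/export for the cellular network, seeded synthetic-data
    generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
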