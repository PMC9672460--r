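Package: saapk
Title: Whole-Body PBPK Simulation and Clinical Pharmacokinetic Analysis of
    Salvianolic Acid A
Version: 0.1.0
Authors@R:
    person("saapk", "maintainers", email = "saapk@example.org",
           role = c("aut", "cre"))
Description: A transporter-saturable whole-body physiologically based
    pharmacokinetic (PBPK) simulator for intravenously infused salvianolic
    acid A, together with the clinical analysis pipeline of a first-in-human
    ascending-dose study design: non-compartmental analysis (NCA) of
    concentration-time profiles, the power-model dose-proportionality
    criterion with bioequivalence-scaled acceptance ranges, Monte-Carlo
    virtual-population trials, and a synthetic-trial generator so the whole
    pipeline runs end-to-end without any external data. Tissues are
    permeability-limited (vascular and extravascular sub-compartments);
    hepatic uptake (OATP1B1) and biliary efflux (P-gp) follow
    Michaelis-Menten kinetics; tissue:plasma partition coefficients can be
    computed by the Rodgers-Leahy-Rowland tissue-composition method. The
    stiff ODE system is integrated with a fourth-order Rosenbrock method
    implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
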