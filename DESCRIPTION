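Package: bnctsim
Title: Neutron Transport and Reaction Kinematics for Boron Neutron
    Capture Therapy Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale physics toolkit for boron neutron capture therapy
    (BNCT) source and dose studies. Provides embedded nuclear constants
    (masses, Q-values, thermal-point cross sections), closed-form two-body
    reaction kinematics for the B-10(n,alpha)Li-7 capture channels and the
    D-D / D-T fusion sources with a numeric four-momentum conservation
    oracle, the space-charge-limited (Child-Langmuir) ion-extraction gap
    design relation for a compact neutron generator, and a from-scratch
    Monte Carlo neutron transport and dose-scoring engine for a
    boron-loaded soft-tissue cylinder with free-gas thermal scattering,
    1/v capture, and boron versus non-boron depth-dose decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    graphics,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
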