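Package: pbpkro
Title: Preclinical-to-Clinical Dose Prediction by PBPK and Receptor Occupancy Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts a first-in-human clinically effective oral dose for a
    receptor antagonist from preclinical data. Provides non-compartmental
    analysis of animal concentration-time profiles, human clearance and
    volume-of-distribution extrapolation by six established interspecies
    methods (two-species allometry, the fu-corrected intercept method,
    well-stirred IVIVE with and without empirical scaling factors, single
    species scaling, the rat-dog-human proportionality equation and the
    Oie-Tozer method), a whole-body perfusion-limited PBPK model with
    Rodgers-Rowland tissue partitioning linked to receptor occupancy through
    an Emax model, a minimum effective dose search under a trough-occupancy
    criterion with virtual-population trials, and retrospective fold-error
    accuracy evaluation. Synthetic-data generators supply concentration-time
    profiles, virtual compounds and virtual populations for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
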