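Package: mcifki
Title: Model-Corrected Input Functions and Cerebral FDG Uptake Rates from
    Dynamic PET Time-Activity Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates a model-corrected blood input function (MCIF) from
    image-derived left-ventricular blood-pool and myocardium time-activity
    curves of dynamic FDG PET studies in small animals, using a 15-parameter
    dual-output two-tissue compartment model with spillover and
    partial-volume corrections, and uses the MCIF to compute regional
    cerebral FDG uptake rate constants Ki with a four-parameter tissue model.
    Includes the seven-parameter Feng arterial input model with constrained
    fitting to discrete blood samples, Patlak graphical analysis as an
    independent check, Bland-Altman and paired-t agreement statistics, and a
    digital-rat phantom that simulates blood, myocardium and regional brain
    curves on the standard 23-frame/60-minute schedule for validation
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    lhs,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
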