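Package: iopgaze
Title: Gaze- and Eyelid-Dependent Intraocular Pressure from Continuous Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for continuous intraocular-pressure (IOP)
    telemetry recorded during gaze-direction and eyelid-closure protocols.
    Provides epoch-locked window extraction with transient trimming,
    baseline-referenced IOP responses (delta IOP), within-epoch time-course
    statistics, fully within-subject repeated-measures ANOVA with
    Greenhouse-Geisser sphericity correction, Bonferroni-Holm corrected
    post-hoc contrasts, vertical-gaze composites and eyelid comparisons, plus
    a synthetic telemetry simulator (ocular pulse, saccadic transients,
    antenna dropout, cough artifacts) with known ground truth for parameter
    recovery and type-I-error validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
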