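Package: asscreen
Title: Cost-Effectiveness of Echocardiographic Screening for Aortic Stenosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic Markov cohort model of one-time transthoracic
    echocardiography screening for aortic stenosis in geriatric populations,
    from the perspective of a publicly funded healthcare system. Implements
    diagnosed and undiagnosed disease-severity states, index hospitalization,
    transcatheter aortic valve replacement (TAVR) with procedural
    complications, tunnelled post-stroke states, monthly cycles with
    discounted cost and QALY accrual, health-state calibration via relative
    risks and prevalence targets, a synthetic Gompertz-Makeham life table,
    probabilistic sensitivity analysis with distributional parameter
    sampling, and ICER/NMB/CEAC summaries. A vectorised individual-level
    microsimulation is included for cross-validation of the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
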