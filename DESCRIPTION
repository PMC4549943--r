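Package: fetaltdi
Title: Automated Analysis of Fetal Myocardial Tissue Doppler Velocity Traces
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for ECG-free analysis of color tissue-Doppler myocardial
    velocity traces of the fetal heart. Segments each cardiac cycle into six
    phases (atrial contraction, pre-ejection, ejection, post-ejection, rapid
    filling, slow filling) from shifts in the acceleration trace, extracts
    peak myocardial velocities (Sm, Em, Am) and phase durations, grades trace
    quality with a three-level acceleration score, and studies the effect of
    region-of-interest (ROI) size on measured velocities and time intervals.
    Includes a synthetic fetal atrioventricular-plane velocity-field generator
    with exact ground-truth event times, plus a command-line interface for
    simulation, analysis, scoring and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
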