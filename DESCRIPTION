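Package: infanterp
Title: Infant Own-Name ERP Pipeline with Synthetic EEG Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for an infant auditory/visual
    event-related potential (ERP) experiment in which 5-month-olds hear their
    own name or a stranger's name and then see a novel object. Provides the
    fixed experimental design (10-20 montage, constrained trial schedules,
    regions of interest and analysis windows), a synthetic infant-EEG cohort
    generator (1/f background noise, Hann-bump ERP components with
    group/condition effect structure, blink and movement artifacts),
    preprocessing (zero-phase FIR band-pass, linked-mastoid re-reference,
    epoching, baseline correction, gliding-window artifact rejection, subject
    inclusion), ERP measurement (windowed mean amplitude, negative peak
    amplitude/latency over ROIs), and the mixed-design statistical battery
    (balanced mixed ANOVA with partial eta squared, Scheffe and t post hocs,
    Wilcoxon signed-rank, split-half and median-split controls).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
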