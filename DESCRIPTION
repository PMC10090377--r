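Package: mprtws
Title: Multi-Parameter Real-Time Warning Score for Clinical Deterioration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a multi-parameter real-time warning score (MPRT-WS)
    over nine continuously monitored vital signs (heart rate, oxygen
    saturation, respiratory rate, systolic and diastolic blood pressure,
    temperature, stroke volume, cardiac output, and systemic vascular
    resistance), with per-parameter 0-3 band scoring, four-level risk
    aggregation (Low/Medium/High/Urgent), and a temporal confirmation rule
    requiring consecutive abnormal readings within a bounded time window.
    Includes a five-parameter NEWS comparator, cohort-level evaluation
    statistics (level distributions, sensitivity, alert lead times,
    chi-square and Fisher exact comparisons, per-parameter attribution,
    diagnosis-group segmentation), a seeded simulator of wearable
    vital-sign streams with stable and deteriorating trajectories, and a
    command-line interface for reproducible runs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
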