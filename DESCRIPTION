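Package: brainaging
Title: Aging Slopes, Bootstrap Confidence Intervals and Normative Tables
    for Regional Brain Volumes
Version: 0.1.0
Authors@R:
    person("GARD", "Replication Project", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Cross-sectional analysis of regional brain-volume aging in
    cognitively normal elderly cohorts. Normalizes FreeSurfer-derived
    regional volumes by intracranial volume, estimates group-stratified
    aging slopes as annual percent change with percentile-bootstrap
    confidence intervals, compares groups by confidence-interval overlap,
    quantifies APOE epsilon-4 effects as bootstrapped slope differences,
    and builds normative volume tables stratified by ethnicity, sex and
    5-year age bin. Includes a synthetic-cohort generator emulating the
    published cohort structure so the full pipeline is testable without
    restricted data, parsers for FreeSurfer aseg/aparc stats files, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
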