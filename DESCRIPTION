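Package: engram
Title: Ensemble Detection and Reactivation Analysis for Calcium-Imaging
    Fear-Memory Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for miniscope calcium-imaging studies of
    hippocampal fear-memory ensembles. Classifies freezing behavior from
    pose tracks (online closed-loop and post-hoc windowed criteria),
    schedules behavior-conditioned light-delivery (tagging) epochs for
    fear-conditioning protocols, extracts binary calcium-event rasters
    from fluorescence traces, assigns cells to period-tuned ensembles by
    activity ranking and by a circular-shift permutation test, and
    quantifies ensemble overlap (bootstrap percentile verdicts),
    cross-session reactivation (relative tracked fraction, freezing-bout
    activity ratios) and pairwise event correlations against circular-shift
    nulls. Includes a seeded synthetic-session generator with planted
    ground-truth ensembles so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
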