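Package: nvsacc
Title: Saccade Detection and Nonparametric Factorial Analysis for
    Non-Visual Cognitive Task Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying horizontal and vertical saccadic eye
    movements recorded while participants perform non-visual cognitive
    tasks (mental arithmetic, verbal fluency) and rest. Provides reading
    and validation of timestamped gaze sample streams and task event
    logs, exact visual-angle conversion from screen geometry, velocity
    based (I-VT) saccade detection with a configurable independence and
    merging rule, per subject-by-period-by-component aggregation of
    saccade frequency, mean amplitude and mean velocity, and a
    statistics layer with Wilcoxon-Mann-Whitney and chi-square group
    comparisons, normality diagnostics, the Aligned Rank Transform, a
    mixed between/within repeated-measures ANOVA with partial omega
    squared effect sizes, and Tukey post hoc contrasts. A synthetic
    gaze-cohort generator with ground-truth labels makes the whole
    pipeline testable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
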