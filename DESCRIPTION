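Package: impactlevels
Title: Chronic Pain Impact Levels from Pain Interference Scores via
    PRO-Bookmarking
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving and applying severity thresholds on the
    PROMIS pain interference T-score metric using the PRO-Bookmarking
    standard-setting method.  Builds score vignettes from a graded
    response model (GRM) item bank by most-likely-response mapping,
    calibrates them by EAP pattern scoring, converts panelists' bookmark
    placements into individual and modal threshold scores, classifies
    respondents into none/mild/moderate/high impact levels, scores the
    Graded Chronic Pain Scale - Revised (GCPS-R) rubric independently,
    and provides concordance analytics: midrank (tie-corrected) Spearman
    correlation computed directly from a contingency table, one-way
    ANOVA from group summary statistics, and Bonferroni post-hoc
    comparisons.  A seeded synthetic-data module generates item banks,
    respondent response matrices, clinic score samples, panel placements
    and GCPS-R records so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
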