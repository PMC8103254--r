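Package: megdens
Title: Regional Neuroelectric Current-Density Atlas, Empty-Room Correction,
    and Stepwise Discriminant Classification for MEG Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing per-region validated-current counts derived
    from magnetoencephalographic (MEG) recordings. Counts are normalized to
    regional current densities (region count fraction divided by region volume
    fraction), z-scored against a normative atlas, and corrected for the
    scanner's empty-room "dark count" using subject vs. empty-room regional
    correlations. Downstream analyses include sweep-based stepwise linear
    discriminant classification with Wilks' lambda entry/removal, jackknifed
    (leave-one-out) classification with exact fair-coin binomial significance,
    second-step reruns excluding previously selected regions, classifier-score
    Welch tests with Levene variance checks, symptom coincidence and score
    correlations, short- and long-term test-retest reliability, and per-subject
    cortex versus adjacent white-matter-rim chi-square differentials against
    volume-proportional expected counts. A synthetic-cohort generator emulates
    the statistical structure of the solver's per-region count output so the
    whole pipeline is testable without access to restricted recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
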