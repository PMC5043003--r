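Package: cagetrial
Title: Cage-Level Statistical Analysis of Repeated-Dose Rodent Feeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the statistical evaluation of chronic rodent feeding
    trials in which the cage, not the animal, is the experimental unit.
    Implements standardized effect sizes (SES) with 95% confidence intervals
    and their joint significance/relevance classification against biological
    relevance limits, the decision-tree "classical" testing procedure
    (Lilliefors-corrected Kolmogorov-Smirnov and Levene gates, one-way ANOVA
    with Dunnett and post hoc t comparisons against control, Kruskal-Wallis
    with pairwise Wilcoxon), restricted-maximum-likelihood generalized least
    squares with AR(1) within-cage errors for growth and feed series, power
    and sample-size calculations on the SES scale, cross-method concordance
    accounting, and a hierarchical synthetic-trial generator emulating a
    four-group, two-gender, two-animals-per-cage chronic design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    dplyr,
    tidyr,
    tibble,
    ggplot2,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    nlme,
    nortest,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
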