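Package: twindiffcurve
Title: Twin-Differences Specification-Curve Analysis of Parenting and
    Child Antisocial Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying the etiologic origin of associations
    between received parenting and child antisocial behavior with the
    child-based twin-differences design. Provides a bivariate ACE
    (additive genetic, shared environmental, nonshared environmental)
    simulator for family-clustered monozygotic and dizygotic twin pairs
    with a multi-informant measurement layer (reliability, right skew,
    missingness), closed-form expected co-twin difference correlations,
    composite and normalization rules for multi-informant scale scores,
    zygosity-stratified difference-score correlations with Fisher
    confidence intervals, random-intercept multilevel phenotypic models,
    Steiger-type comparison of dependent correlations, and an exhaustive
    specification-curve engine with sample-size-weighted aggregation, a
    four-indicator significance decision rule, and an etiologic scenario
    classifier (environmental, genetic, or genetic plus shared
    environmental mediation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    grDevices,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
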