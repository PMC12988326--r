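Package: defensome
Title: Prokaryotic Defensome Surveys with Homology-Based Restriction-Modification Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for surveying antiviral defense repertoires (defensomes)
    across prokaryotic genome cohorts. Implements a REBASE-style
    restriction-modification (RM) system caller that combines best-hit protein
    homology with gene-neighborhood architecture rules, aggregation of RM
    calls with external defense-annotation tables into per-genome defensomes,
    and the statistical battery used in domain-scale prevalence surveys:
    Wilson intervals, Firth bias-reduced logistic regression with
    phylum-versus-overall-mean contrasts, completeness-adjusted prevalence
    extrapolation, and negative-binomial and hurdle count models of defense
    abundance against growth temperature and genome size. A synthetic-cohort
    generator with recorded ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    MASS,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
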