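Package: starpheno
Title: Structured Tracking of Alcohol Reinforcement (STAR) Phenotyping and
    Operant Session Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing operant alcohol self-administration
    experiments in rodents under the Structured Tracking of Alcohol
    Reinforcement (STAR) framework. Provides event-level processing of
    timestamped session logs (nose-pokes, licks, sipper actuations),
    intake computation in g/kg, lick-microstructure and cumulative-record
    summaries, the operant acquisition state machine, the group-normalized
    Low/High/Compulsive Drinker phenotyping statistic, a permutated
    resampling analysis of phenotype stability as a function of sample
    size, a rank-correlation screen relating brain analyte concentrations
    to drinking behavior, and a synthetic cohort generator with known
    ground truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
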