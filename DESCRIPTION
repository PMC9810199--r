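Package: omopflow
Title: Healthcare Process Mining on the OMOP Common Data Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts process-mining event logs from OMOP Common Data Model
    (CDM v5.3+) table sets for four healthcare process types (inpatient,
    outpatient, emergency room, patient journey), mines clinical pathways with
    a matching-rate based greedy order-selection algorithm, and computes
    process-discovery analytics (directly-follows graphs with frequency and
    performance annotation, trace variants, dotted-chart coordinates, and
    length-of-stay summaries). A synthetic CDM generator with planted ground
    truth (clinical-pathway entries, visit-type Markov chains, emergency-room
    admission mixes, date-only timestamp degradation) makes every stage
    testable without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
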