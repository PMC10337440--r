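Package: paincorpus
Title: Rule-Based Extraction and Annotation of Pain Mentions in Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for building annotated corpora of pain
    mentions from free-text clinical notes. Wildcard lexicon patterns locate
    candidate pain mentions; deterministic contextual rules assign an
    annotation scheme covering correctness, relevance (including negation and
    experiencer status), anatomical location, pain character, and pain
    management. Includes inter-annotator agreement statistics (percent
    agreement and Cohen's kappa), adjudication, corpus-level descriptive
    summaries, sample size calculations for annotation campaigns, and a
    seeded synthetic clinical-note generator that produces gold-standard
    corpora for testing without access to restricted health-record data.
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
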