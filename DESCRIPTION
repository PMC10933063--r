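Package: injurymine
Title: Emerging Injury Issue Detection from Free-Text EMS Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects emerging injury risk issues from free-text emergency
    medical service (EMS) incident narratives. Tokenizes per-incident
    narratives into yearly term-document matrices, ranks candidate injury
    keywords by average annual TF-IDF with a per-term maximum term-frequency
    convention, scores each keyword's yearly document-frequency trajectory on
    average frequency, average acceleration and relative volatility (quintile
    rank scores), and classifies keywords as hazardous, noteworthy or
    diffusion accident terms. A phi-coefficient semantic ego network around
    hazardous keywords is built and decomposed into Louvain communities.
    Includes a synthetic-corpus generator with planted term trajectories and
    planted co-occurrence blocks so every stage can be validated against a
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    Matrix,
    methods,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
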