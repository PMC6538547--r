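Package: collabotag
Title: Collaborating BiLSTM-CRF Taggers for Biomedical Named Entity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiple single-task BiLSTM-CRF named-entity taggers, one per
    biomedical entity type, that exchange encoder outputs during a phased
    training schedule so each entity-type expert learns to suppress the other
    experts' entity types (the CollaboNet scheme). Includes CNN character-level
    word embeddings, word2vec text-format embedding loading, linear-chain CRF
    training and Viterbi decoding, BIO/BIOES tag-scheme handling with repair of
    invalid sequences, exact-match entity-level evaluation, a bio-entity/span
    error taxonomy, and a seeded synthetic-corpus generator with planted
    polysemous tokens for benchmarking the collaboration mechanism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
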