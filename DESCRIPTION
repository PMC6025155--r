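Package: kitm
Title: Knowledge-Involved Topic Modeling for Consumer Health Text
Version: 0.1.0
Authors@R:
    person("OHC", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Knowledge discovery from patient-reported posts in online health
    communities. Provides a lightweight medical knowledge-base container
    (concepts, typed relations, IS_A hierarchy) with readers for
    UMLS-Metathesaurus-style pipe-delimited files and a self-contained toy TSV
    dialect; an Algorithm-style tokenizer and filter chain for narrative
    posts; dictionary-based concept encoding with coarse part-of-speech
    tagging; latent-knowledge expansion by exact-distance graph frontiers;
    Labeled LDA trained with zero-order collapsed variational Bayes (CVB0);
    and the evaluation metrics explicit knowledge rate (EKR), latent
    knowledge rate (LKR), knowledge correlation rate (KCR), and held-out
    perplexity. A synthetic-data module generates toy knowledge bases and
    labeled corpora with known topic structure so the full pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
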