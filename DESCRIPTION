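Package: kbrelex
Title: Knowledge-Base-Reinforced BiLSTM Extraction of Biomedical Entities and Relations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts gene/protein mentions and their semantic relations
    (protein-protein interaction style, eight directed relation types) from
    biomedical text annotated in BioNLP shared-task standoff format. A
    bidirectional LSTM encoder is reinforced with curated knowledge: per-token
    hidden states attend, through a learned bilinear form, over vectors of
    entities that co-participate in biochemical reactions (SBML reaction
    models), and annotation text from UniProt-style records enriches entity
    representations. Includes BIOE sequence tagging with an optional
    linear-chain CRF, softmax relation classification, AdaDelta training, a
    micro-averaged precision/recall/F1 evaluator, and a synthetic-corpus
    generator with controllable lexical and knowledge-base signal for
    ablation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
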