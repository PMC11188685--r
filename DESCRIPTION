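Package: crmlit
Title: Literature Screening for Cis-Regulatory Module Target Genes and
    Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A four-step pipeline for prescreening the biomedical literature
    for descriptions of modular transcription regulation. Step 1 triages
    PubMed abstracts with a data-bootstrapping classifier ensemble aggregated
    by AdaBoost to cope with extreme class imbalance; Step 2 retrieves
    open-access full texts (JATS XML) through a pluggable offline-capable
    transport; Step 3 labels every (gene name, paragraph) pair as describing
    a CRM target gene and/or a regulatory transcription factor using a
    multi-label network trained with a positive- and instance-weighted binary
    cross-entropy loss; Step 4 summarizes the paragraph labels into
    per-article target-gene and TF lists. Includes dictionary gene-mention
    recognition with synonym and stoplist handling, macro ROC/PR evaluation,
    a name-occurrence-counting baseline, and a seeded synthetic-corpus
    generator so the whole pipeline is trainable and testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
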