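Package: qaenc
Title: Question-Answering Encoding Models for Language Neuroscience
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Build and evaluate interpretable question-answering (QA) encoding
    models of brain responses to narrative language. Qualitative theories of
    language selectivity, phrased as yes/no questions, are turned into binary
    text embeddings by annotating transcript windows with a pluggable
    annotator; sparse stability selection compresses a large question bank to
    a compact set; voxelwise (fMRI) and per-lag electrode-wise (ECoG) ridge
    encoding models with FIR delays are fit and scored by held-out prediction
    correlation; the resulting per-question weight maps are evaluated with
    reference-map correlation, condition-average comparison, inter-subject
    consistency and cross-modality agreement, using permutation tests with
    Benjamini-Hochberg false discovery rate correction. A fully deterministic
    synthetic-data generator with planted structure makes every step testable
    without real recordings or LLM calls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
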