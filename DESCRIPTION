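Package: tcnss
Title: Protein Secondary Structure Prediction with a Multiscale
    Bidirectional TCN, BiLSTM Attention and Knowledge Distillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-residue protein secondary structure prediction (3-state and
    8-state DSSP alphabets) from amino-acid sequence alone. Residues are
    featurized by one-hot encoding, physicochemical properties (polarity
    class, net charge, size, hydropathy) and skip-gram word vectors trained
    on the sequence corpus; the predictor stacks a multiscale bidirectional
    dilated causal temporal convolutional network, three bidirectional LSTM
    layers with multi-head self-attention, and a softmax classifier, and can
    be trained with knowledge distillation from cached teacher logits via a
    temperature-softened Kullback-Leibler loss. Includes the SOV99
    segment-overlap score, Q3/Q8 accuracy and micro-averaged multiclass AUC,
    plus a semi-Markov synthetic sequence generator so the whole pipeline is
    exercisable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
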