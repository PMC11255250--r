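# tcnss

Per-residue protein secondary structure prediction in R — 3-state (H/E/C)
or 8-state DSSP (H/G/I/E/B/T/S/C) — from amino-acid sequence alone, for
structural bioinformaticians who want a fully inspectable, CPU-scale
implementation of a modern deep sequence-labeling stack rather than an
opaque pretrained binary.

## What it implements

* **Featurization**: one-hot encoding (21 symbols, `X` for unknown),
  physicochemical properties (polarity class, net charge at pH 7, scaled
  molecular weight, scaled Kyte–Doolittle hydropathy), and skip-gram
  (word2vec) k-mer embeddings trained on the input corpus, concatenated per
  residue; sliding-window segmentation for local-feature experiments.
* **Model**: an improved temporal convolutional network — residual blocks of
  three causal dilated convolutions at multiple dilation scales (default
  `[1, 9, 81, 729, 6561]`), run bidirectionally with independent forward and
  backward branches, fused by 1×1 convolutions — feeding three bidirectional
  LSTM layers with 3-head scaled dot-product self-attention
  (`Attention(Q,K,V) = softmax(QKᵀ/√d_k)V`) and a softmax classifier. All
  forward and backward passes are hand-written (R + an Rcpp LSTM kernel)
  and gradient-checked.
* **Knowledge distillation**: the blended loss
  `(1−α)·CE + α·ρ²·KL(σ(Z_T/ρ) ‖ σ(Z_S/ρ))` with temperature ρ (default 2)
  and weight α (default 0.2); teachers are supplied as cached per-residue
  logits (JSON-lines or TSV), never run in-process.
* **Metrics**: Q3/Q8 accuracy, the SOV99 segment-overlap score with its
  half-shorter-segment boundary tolerance δ, and micro-averaged one-vs-rest
  multiclass AUC — each validated against independent brute-force oracles.
* **Synthetic data**: a semi-Markov generator (geometric segment dwell,
  state-dependent residue emissions, presets from deterministic to heavily
  overlapping) plus an oracle teacher, so the whole pipeline runs without
  external datasets.
* **Workflow**: deterministic training (Adam, whole-sequence batches),
  JSON checkpoints, tidy `predict()` output, `evaluate()` reports,
  scale/α sensitivity sweeps, `tidy()`/`glance()`/`autoplot()` methods, and
  a thin CLI (`inst/cli/tcnss.R`).

## Worked example

Generate a synthetic corpus, train a compact distilled model, and evaluate:

```r
library(tcnss)

corpus  <- generate_records(generator_config(n_records = 40,
                                             length_range = c(30, 60),
                                             seed = 42))
sp      <- split_records(corpus, train_fraction = 0.7, seed = 1)
teacher <- oracle_teacher(sp$train, seed = 2)

cfg <- model_config(scales = c(1, 9), channels = 8, text_width = 16,
                    tcn_hidden = 16, lstm_hidden = 12, embed_dim = 8,
                    w2v_epochs = 5, epochs = 60, lr = 3e-3,
                    distill = TRUE, seed = 1)
fit <- train(sp$train, cfg = cfg, teacher = teacher)
fit
#> <ssp_fit Q3: 60 epochs (best 60), final train acc 93.4%, 18835 params, 36.9s>

evaluate_fit(fit, sp$test)
#> <metrics_report: 12 records, 537 residues | ACC 74.9%, SOV99 65.8, MiAUC 0.8953 (Q3)>

head(predict(fit, sp$test[1, ]), 5)
#> # A tibble: 5 × 7
#>   id     position residue   p_H      p_E     p_C label
#>   <chr>     <int> <chr>   <dbl>    <dbl>   <dbl> <chr>
#> 1 syn003        1 K       0.991 0.00239  0.00652 H
#> 2 syn003        2 Q       0.994 0.000837 0.00471 H
#> 3 syn003        3 Q       0.991 0.000698 0.00785 H
#> 4 syn003        4 E       0.981 0.000960 0.0183  H
#> 5 syn003        5 D       0.963 0.00154  0.0353  H
```

The test accuracy (74.9%) sits between the per-residue Bayes limit of the
emission model and chance; SOV99 (65.8) additionally rewards getting whole
helix/strand segments right, and MiAUC (0.895) summarizes the ranked
probabilities over all (position, class) decisions. On the `"easy"` preset,
where labels are a deterministic function of residues, the same
architecture trains to 100%.

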