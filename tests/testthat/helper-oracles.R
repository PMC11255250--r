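# Independent oracles used across the suite. These are deliberately naive
# implementations written directly from the defining formulas, kept separate
# from the production code paths they check.

# Brute-force SOV99: explicit position-set arithmetic over every pair of
# observed/predicted segments.
sov99_oracle <- function(obs, pred) {
  stopifnot(nchar(obs) == nchar(pred))
  seg_list <- function(x) {
    ch <- strsplit(x, "", fixed = TRUE)[[1]]
    if (length(ch) == 0) return(list())
    r <- rle(ch)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1
    lapply(seq_along(r$values), function(i) {
      list(state = r$values[i], pos = s[i]:e[i])
    })
  }
  so <- seg_list(obs)
  sp <- seg_list(pred)
  num <- 0
  N <- 0
  for (s1 in so) {
    partners <- Filter(function(s2) {
      s2$state == s1$state && length(intersect(s1$pos, s2$pos)) > 0
    }, sp)
    len1 <- length(s1$pos)
    if (length(partners) == 0) {
      N <- N + len1
      next
    }
    for (s2 in partners) {
      len2 <- length(s2$pos)
      minov <- length(intersect(s1$pos, s2$pos))
      maxov <- length(union(s1$pos, s2$pos))
      delta <- min(maxov - minov, minov, len1 %/% 2, len2 %/% 2)
      num <- num + (minov + delta) / maxov * len1
      N <- N + len1
    }
  }
  if (N == 0) 0 else 100 * num / N
}

# Pairwise-comparison AUC: probability that a random positive outscores a
# random negative, ties counted one half.
auc_pairwise_oracle <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Hand-unrolled LSTM recursion (sigmoid input/forget/output gates, tanh
# candidate, c_t = f*c_{t-1} + i*g, h_t = tanh(c_t)*o).
lstm_oracle <- function(X, Wx, Wh, b) {
  H <- nrow(Wh)
  sig <- function(x) 1 / (1 + exp(-x))
  h_prev <- rep(0, H)
  c_prev <- rep(0, H)
  out <- matrix(0, nrow(X), H)
  for (t in seq_len(nrow(X))) {
    z <- as.numeric(X[t, ] %*% Wx + h_prev %*% Wh) + b
    i <- sig(z[1:H])
    f <- sig(z[H + 1:H])
    o <- sig(z[2 * H + 1:H])
    g <- tanh(z[3 * H + 1:H])
    c_t <- f * c_prev + i * g
    h_t <- tanh(c_t) * o
    out[t, ] <- h_t
    h_prev <- h_t
    c_prev <- c_t
  }
  out
}

random_labels <- function(L, states) {
  paste(sample(states, L, replace = TRUE), collapse = "")
}

# Compact architecture used wherever a test trains or runs the network; small
# enough for CPU unit tests, still exercising every stage (two scales, three
# BiLSTM layers, three heads).
small_cfg <- function(epochs = 40, seed = 1, ...) {
  model_config(scales = c(1, 9), channels = 8, text_width = 16,
               tcn_hidden = 16, lstm_layers = 3, lstm_hidden = 12, heads = 3,
               embed_dim = 8, w2v_epochs = 5, dropout = 0.1, epochs = epochs,
               batch_size = 8, lr = 3e-3, seed = seed, ...)
}

# Tiny feature matrix + initialized model for forward-pass tests.
tiny_model <- function(L = 8, D = 10, seed = 3, ...) {
  cfg <- model_config(scales = c(1, 3), channels = 4, text_width = 6,
                      tcn_hidden = 5, lstm_layers = 2, lstm_hidden = 4,
                      heads = 2, dropout = 0, seed = seed, ...)
  set.seed(seed)
  list(cfg = cfg, X = matrix(rnorm(L * D), L, D),
       model = init_model(cfg, D))
}
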