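test_that("bilstm matches the hand-unrolled gate recursion", {
  cfg <- model_config(scales = 1, channels = 4, text_width = 5,
                      tcn_hidden = 5, lstm_layers = 1, lstm_hidden = 3,
                      heads = 1, dropout = 0, seed = 6)
  set.seed(21)
  for (rep in 1:20) {
    m <- init_model(cfg, 8)
    L <- sample(1:5, 1)
    x <- matrix(rnorm(L * 5), L, 5)
    pf <- m$params$lstm[[1]]$fwd
    pb <- m$params$lstm[[1]]$bwd
    expected <- cbind(
      lstm_oracle(x, pf$Wx, pf$Wh, pf$b),
      lstm_oracle(x[L:1, , drop = FALSE], pb$Wx, pb$Wh, pb$b)[L:1, ,
                                                             drop = FALSE]
    )
    expect_equal(bilstm(x, m), expected, tolerance = 1e-10)
  }
})

test_that("bilstm with all-zero gates outputs zeros; width is 2W", {
  cfg <- model_config(scales = 1, channels = 4, text_width = 5,
                      tcn_hidden = 5, lstm_layers = 2, lstm_hidden = 4,
                      heads = 2, dropout = 0, seed = 3)
  m <- init_model(cfg, 8)
  for (l in 1:2) {
    for (dir in c("fwd", "bwd")) {
      m$params$lstm[[l]][[dir]]$Wx[] <- 0
      m$params$lstm[[l]][[dir]]$Wh[] <- 0
      m$params$lstm[[l]][[dir]]$b[] <- 0
    }
  }
  x <- matrix(rnorm(20), 4, 5)
  out <- bilstm(x, m)
  # zero gates: i = f = o = 0.5, candidate tanh(0) = 0, so c and h stay 0
  expect_equal(out, matrix(0, 4, 8))
  expect_equal(ncol(out), 2L * cfg$lstm_hidden)
})

test_that("multi_head_attention is row-stochastic with the expected limits", {
  tm <- tiny_model(L = 6)
  h <- matrix(rnorm(6 * 8), 6, 8)

  # L = 1: the single attention weight is exactly 1
  r1 <- multi_head_attention(h[1, , drop = FALSE], tm$model,
                             return_weights = TRUE)
  for (w in r1$weights) expect_equal(w, matrix(1, 1, 1))

  # identical keys at all positions: uniform weights 1/L
  h_const <- matrix(rep(rnorm(8), each = 6), 6, 8)
  rc <- multi_head_attention(h_const, tm$model, return_weights = TRUE)
  for (w in rc$weights) expect_equal(w, matrix(1 / 6, 6, 6))

  # all attention rows sum to 1, fuzzed over shapes
  set.seed(31)
  for (rep in 1:10) {
    L <- sample(1:12, 1)
    hh <- matrix(rnorm(L * 8), L, 8)
    rr <- multi_head_attention(hh, tm$model, return_weights = TRUE)
    for (w in rr$weights) {
      expect_equal(unname(rowSums(w)), rep(1, L), tolerance = 1e-12)
    }
    expect_equal(dim(rr$out), dim(hh))
  }
})

test_that("scaled-identity projections at large scale give near-identity attention", {
  cfg <- model_config(scales = 1, channels = 4, text_width = 5,
                      tcn_hidden = 5, lstm_layers = 1, lstm_hidden = 3,
                      heads = 1, dropout = 0, seed = 5)
  m <- init_model(cfg, 8)
  M <- 6  # = 2 * lstm_hidden; single head, d_k = M
  s <- 50
  m$params$attn$WQ[[1]] <- diag(M) * sqrt(s)
  m$params$attn$WK[[1]] <- diag(M) * sqrt(s)
  m$params$attn$WV[[1]] <- diag(M)
  m$params$attn$Wo <- diag(M)
  h <- diag(M)  # orthogonal rows: scores s/sqrt(d_k) on the diagonal, 0 off
  r <- multi_head_attention(h, m, return_weights = TRUE)
  A <- r$weights[[1]]
  # oracle: direct softmax of the score matrix
  S <- (h %*% m$params$attn$WQ[[1]]) %*% t(h %*% m$params$attn$WK[[1]]) /
    sqrt(M)
  A_oracle <- exp(S - apply(S, 1, max))
  A_oracle <- A_oracle / rowSums(A_oracle)
  expect_equal(A, A_oracle, tolerance = 1e-12)
  expect_lt(max(A[row(A) != col(A)]), 1e-8)
})

test_that("classify produces probability rows with the softmax limits", {
  tm <- tiny_model(L = 5)
  m <- tm$model
  W2 <- 2 * tm$cfg$lstm_hidden
  hb <- matrix(rnorm(5 * W2), 5, W2)
  ha <- matrix(rnorm(5 * W2), 5, W2)

  # all-zero classifier: uniform rows
  m0 <- m
  m0$params$cls$conv$W[] <- 0; m0$params$cls$conv$b[] <- 0
  m0$params$cls$dense$W[] <- 0; m0$params$cls$dense$b[] <- 0
  expect_equal(classify(hb, ha, m0), matrix(1 / 3, 5, 3))

  # bias (10, 0, 0): softmax oracle
  m0$params$cls$dense$b <- c(10, 0, 0)
  expected <- exp(c(10, 0, 0)) / sum(exp(c(10, 0, 0)))
  p <- classify(hb, ha, m0)
  expect_equal(p[1, ], expected, tolerance = 1e-12)
  expect_equal(p[3, 2], 4.5397e-05, tolerance = 1e-4)

  # random parameters: rows always sum to 1
  set.seed(41)
  for (rep in 1:10) {
    p <- classify(matrix(rnorm(5 * W2), 5, W2),
                  matrix(rnorm(5 * W2), 5, W2), m)
    expect_equal(unname(rowSums(p)), rep(1, 5), tolerance = 1e-9)
  }
})

test_that("the full forward pass preserves length and is repeatable", {
  tm <- tiny_model(L = 1)
  p1 <- forward_probs(tm$model, tm$X)
  expect_equal(dim(p1), c(1L, 3L))

  tm8 <- tiny_model(L = 8)
  pa <- forward_probs(tm8$model, tm8$X)
  pb <- forward_probs(tm8$model, tm8$X)
  expect_identical(pa, pb)
  expect_equal(unname(rowSums(pa)), rep(1, 8), tolerance = 1e-9)

  lab <- tcnss:::probs_to_labels(pa, q3_alphabet())
  expect_equal(nchar(lab), 8)
  expect_true(all(strsplit(lab, "")[[1]] %in% c("H", "E", "C")))

  expect_error(forward_probs(tm8$model, tm8$X[0, , drop = FALSE]), "empty")
  expect_error(forward_probs(tm8$model, tm8$X[, 1:5]), "feature width")
})

test_that("analytic gradients match finite differences through every stage", {
  cfg <- model_config(scales = c(1, 3), channels = 4, text_width = 6,
                      tcn_hidden = 5, lstm_layers = 2, lstm_hidden = 4,
                      heads = 3, embed_dim = 4, dropout = 0, seed = 7,
                      rho = 2, alpha = 0.3, distill = TRUE)
  set.seed(11)
  L <- 9; D <- 10; K <- 3
  X <- matrix(rnorm(L * D), L, D)
  y_idx <- sample(K, L, replace = TRUE)
  zt <- matrix(rnorm(L * K), L, K)
  m <- init_model(cfg, D)
  loss_of <- function(params) {
    fw <- tcnss:::nn_fwd(params, X, cfg, training = TRUE)
    hard <- -mean(log(fw$probs[cbind(1:L, y_idx)] + 1e-12))
    (1 - cfg$alpha) * hard + cfg$alpha * kd_loss(fw$logits, zt, cfg$rho)
  }
  fw <- tcnss:::nn_fwd(m$params, X, cfg, training = TRUE)
  yi <- matrix(0, L, K); yi[cbind(1:L, y_idx)] <- 1
  dlog <- (1 - cfg$alpha) * (fw$probs - yi) / L +
    cfg$alpha * tcnss:::kd_loss_grad(fw$logits, zt, cfg$rho)
  g <- tcnss:::nn_bwd(fw$cache, dlog)$grads

  leaves <- list()
  walk <- function(p, gr, path) {
    if (is.list(p)) {
      nms <- names(p); if (is.null(nms)) nms <- as.character(seq_along(p))
      for (i in seq_along(p)) {
        if (is.null(p[[i]])) next
        walk(p[[i]], gr[[i]], c(path, i))
      }
    } else {
      leaves[[length(leaves) + 1]] <<- list(path = path, n = length(p),
                                            g = gr)
    }
  }
  walk(m$params, g, integer(0))
  set.seed(99)
  eps <- 1e-5
  for (lf in sample(leaves, 30)) {
    j <- sample(lf$n, 1)
    bump <- function(delta) {
      p2 <- m$params
      node <- p2
      expr <- lf$path
      setleaf <- function(x, keys) {
        if (length(keys) == 1) {
          x[[keys]][j] <- x[[keys]][j] + delta
          return(x)
        }
        x[[keys[1]]] <- setleaf(x[[keys[1]]], keys[-1])
        x
      }
      setleaf(p2, lf$path)
    }
    fd <- (loss_of(bump(eps)) - loss_of(bump(-eps))) / (2 * eps)
    rel <- abs(fd - lf$g[j]) / max(1e-4, abs(fd) + abs(lf$g[j]))
    expect_lt(rel, 1e-4)
  }
})
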