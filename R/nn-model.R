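#' Model and training configuration
#'
#' All architecture and training hyperparameters with their defaults. The
#' multiscale dilation list `[1, 9, 81, 729, 6561]` and the distillation
#' blend `alpha = 0.2` are the reference settings; everything is overridable.
#'
#' @param alphabet `"Q3"` or `"Q8"` target alphabet.
#' @param k,w2v_window,embed_dim,w2v_epochs,w2v_negative skip-gram
#'   featurization knobs (k-mer size, context window, vector dimension,
#'   epochs, negative samples).
#' @param scales dilation factor per TCN scale (strictly increasing).
#' @param kernel_size convolution kernel size per scale.
#' @param channels channels per residual block.
#' @param conv_layers convolution layers per residual block.
#' @param text_width width of the learned input projection (TextEmbedding).
#' @param tcn_hidden output width H of the improved TCN.
#' @param lstm_layers,lstm_hidden stacked BiLSTM depth and per-direction
#'   hidden width.
#' @param heads attention heads.
#' @param dropout dropout rate (embedding, conv stages, inter-LSTM).
#' @param distill enable knowledge distillation.
#' @param rho distillation temperature.
#' @param alpha soft-loss blend weight in `[0, 1]`.
#' @param kd_rho2_scale multiply the soft loss by `rho^2` (the classic
#'   convention keeping soft-gradient magnitude temperature-invariant).
#' @param lr,batch_size,epochs,patience Adam learning rate, sequences per
#'   batch, training epochs, early-stopping patience (epochs without
#'   validation improvement; `Inf` disables).
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return a `model_config` list.
#' @export
model_config <- function(alphabet = c("Q3", "Q8"),
                         k = 1L, w2v_window = 5L, embed_dim = 16L,
                         w2v_epochs = 20L, w2v_negative = 5L,
                         scales = c(1L, 9L, 81L, 729L, 6561L),
                         kernel_size = 3L, channels = 32L, conv_layers = 3L,
                         text_width = 64L, tcn_hidden = 64L,
                         lstm_layers = 3L, lstm_hidden = 64L, heads = 3L,
                         dropout = 0.2,
                         distill = FALSE, rho = 2, alpha = 0.2,
                         kd_rho2_scale = TRUE,
                         lr = 1e-3, batch_size = 8L, epochs = 50L,
                         patience = Inf, seed = 1L) {
  alphabet <- match.arg(alphabet)
  if (length(scales) == 0) stop("need at least one scale", call. = FALSE)
  if (any(diff(scales) <= 0) || any(scales < 1)) {
    stop("scales must be strictly increasing and >= 1", call. = FALSE)
  }
  if (rho <= 0) stop("rho must be positive", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  structure(as.list(environment()), class = "model_config")
}

#' Read a model configuration from YAML or JSON
#'
#' Unknown keys are rejected; omitted keys take the documented defaults.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @return a [model_config()].
#' @export
read_model_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(model_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(model_config, vals)
}

cfg_alphabet <- function(cfg) {
  if (cfg$alphabet == "Q8") q8_alphabet() else q3_alphabet()
}

glorot <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
}

init_linear <- function(fin, fout) list(W = glorot(fin, fout),
                                        b = rep(0, fout))

init_conv <- function(fin, fout, k) {
  lim <- sqrt(6 / (fin * k + fout))  # fan-in counts all k taps
  list(W = lapply(seq_len(k), function(i) {
         matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
       }),
       b = rep(0, fout))
}

init_block <- function(fin, ch, k, n_layers) {
  widths <- c(fin, rep(ch, n_layers))
  list(conv = lapply(seq_len(n_layers), function(l) {
         init_conv(widths[l], widths[l + 1], k)
       }),
       proj = if (fin != ch) list(W = glorot(fin, ch)) else NULL)
}

init_branch <- function(fin, cfg) {
  list(blocks = lapply(cfg$scales, function(s) {
         init_block(fin, cfg$channels, cfg$kernel_size, cfg$conv_layers)
       }),
       fuse = init_linear(length(cfg$scales) * cfg$channels, cfg$tcn_hidden))
}

init_lstm_dir <- function(fin, H) {
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias opens the memory path early
  list(Wx = glorot(fin, 4 * H), Wh = glorot(H, 4 * H), b = b)
}

#' Initialize model parameters
#'
#' Fan-in/fan-out scaled uniform initialization, fully determined by
#' `cfg$seed`. The two TCN branches have identical shapes but independent
#' parameters; the same holds for the two LSTM directions.
#'
#' @param cfg a [model_config()].
#' @param feature_dim width D of the per-residue feature rows.
#' @return an `ssp_model` list with elements `params`, `cfg`, `feature_dim`.
#' @export
init_model <- function(cfg, feature_dim) {
  K <- length(cfg_alphabet(cfg))
  with_local_seed(cfg$seed, {
    H <- cfg$tcn_hidden
    W2 <- 2L * cfg$lstm_hidden
    dk <- max(1L, W2 %/% cfg$heads)
    lstm_in <- c(H, rep(W2, cfg$lstm_layers - 1))
    params <- list(
      embed = init_linear(feature_dim, cfg$text_width),
      tcn = list(
        fwd = init_branch(cfg$text_width, cfg),
        bwd = init_branch(cfg$text_width, cfg),
        conv = init_linear(H, H),
        dense = init_linear(H, H),
        bn = list(gamma = rep(1, H), beta = rep(0, H))
      ),
      lstm = lapply(seq_len(cfg$lstm_layers), function(l) {
        list(fwd = init_lstm_dir(lstm_in[l], cfg$lstm_hidden),
             bwd = init_lstm_dir(lstm_in[l], cfg$lstm_hidden))
      }),
      attn = list(
        WQ = lapply(seq_len(cfg$heads), function(i) glorot(W2, dk)),
        WK = lapply(seq_len(cfg$heads), function(i) glorot(W2, dk)),
        WV = lapply(seq_len(cfg$heads), function(i) glorot(W2, dk)),
        Wo = glorot(cfg$heads * dk, W2)
      ),
      cls = list(conv = init_linear(2L * W2, W2),
                 dense = init_linear(W2, K))
    )
    structure(list(params = params, cfg = cfg, feature_dim = feature_dim),
              class = "ssp_model")
  })
}

#' @export
print.ssp_model <- function(x, ...) {
  cat(sprintf(
    "<ssp_model %s: D=%d, scales [%s], channels %d, H=%d, BiLSTM %dx%d, %d heads>\n",
    x$cfg$alphabet, x$feature_dim, paste(x$cfg$scales, collapse = ","),
    x$cfg$channels, x$cfg$tcn_hidden, x$cfg$lstm_layers, x$cfg$lstm_hidden,
    x$cfg$heads))
  invisible(x)
}

rev_rows <- function(x) x[nrow(x):1, , drop = FALSE]

## ---- residual block -------------------------------------------------------

rb_fwd <- function(x, p, dilation, dropout, training) {
  h <- x
  stages <- vector("list", length(p$conv))
  for (l in seq_along(p$conv)) {
    cv <- conv_fwd(h, p$conv[[l]]$W, p$conv[[l]]$b, dilation)
    ac <- relu_fwd(cv$out)
    dp <- dropout_fwd(ac$out, dropout, training)
    stages[[l]] <- list(conv = cv$cache, relu = ac$cache, drop = dp$cache)
    h <- dp$out
  }
  if (is.null(p$proj)) {
    skip <- x
  } else {
    skip <- x %*% p$proj$W
  }
  list(out = h + skip, cache = list(stages = stages, x = x, p = p))
}

rb_bwd <- function(cache, dout) {
  p <- cache$p
  g <- list(conv = vector("list", length(p$conv)), proj = NULL)
  if (is.null(p$proj)) {
    dx <- dout
  } else {
    dx <- dout %*% t(p$proj$W)
    g$proj <- list(W = t(cache$x) %*% dout)
  }
  dh <- dout
  for (l in rev(seq_along(p$conv))) {
    st <- cache$stages[[l]]
    dh <- dropout_bwd(st$drop, dh)
    dh <- relu_bwd(st$relu, dh)
    cb <- conv_bwd(st$conv, dh)
    g$conv[[l]] <- list(W = cb$dW, b = cb$db)
    dh <- cb$dx
  }
  list(dx = dx + dh, grads = g)
}

## ---- multiscale branch ----------------------------------------------------

ms_fwd <- function(x, bp, cfg, training) {
  outs <- vector("list", length(cfg$scales))
  caches <- vector("list", length(cfg$scales))
  for (s in seq_along(cfg$scales)) {
    rb <- rb_fwd(x, bp$blocks[[s]], cfg$scales[s], cfg$dropout, training)
    outs[[s]] <- rb$out
    caches[[s]] <- rb$cache
  }
  cat_out <- do.call(cbind, outs)
  fuse <- linear_fwd(cat_out, bp$fuse$W, bp$fuse$b)
  list(out = fuse$out,
       cache = list(blocks = caches, fuse = fuse$cache,
                    widths = vapply(outs, ncol, integer(1))))
}

ms_bwd <- function(cache, dout) {
  fl <- linear_bwd(cache$fuse, dout)
  g <- list(blocks = vector("list", length(cache$blocks)),
            fuse = list(W = fl$dW, b = fl$db))
  dx <- NULL
  col0 <- 0L
  for (s in seq_along(cache$blocks)) {
    w <- cache$widths[s]
    dblk <- fl$dx[, (col0 + 1):(col0 + w), drop = FALSE]
    col0 <- col0 + w
    rb <- rb_bwd(cache$blocks[[s]], dblk)
    g$blocks[[s]] <- rb$grads
    dx <- if (is.null(dx)) rb$dx else dx + rb$dx
  }
  list(dx = dx, grads = g)
}

## ---- improved TCN ---------------------------------------------------------

tcn_fwd <- function(x, tp, cfg, training) {
  fw <- ms_fwd(x, tp$fwd, cfg, training)
  bw <- ms_fwd(rev_rows(x), tp$bwd, cfg, training)
  y <- fw$out + rev_rows(bw$out)
  cv <- linear_fwd(y, tp$conv$W, tp$conv$b)
  de <- linear_fwd(cv$out, tp$dense$W, tp$dense$b)
  ac <- relu_fwd(de$out)
  bn <- bn_fwd(ac$out, tp$bn$gamma, tp$bn$beta)
  list(out = bn$out,
       cache = list(fw = fw$cache, bw = bw$cache, conv = cv$cache,
                    dense = de$cache, relu = ac$cache, bn = bn$cache))
}

tcn_bwd <- function(cache, dout) {
  bn <- bn_bwd(cache$bn, dout)
  dh <- relu_bwd(cache$relu, bn$dx)
  de <- linear_bwd(cache$dense, dh)
  cv <- linear_bwd(cache$conv, de$dx)
  fw <- ms_bwd(cache$fw, cv$dx)
  bw <- ms_bwd(cache$bw, rev_rows(cv$dx))
  list(dx = fw$dx + rev_rows(bw$dx),
       grads = list(fwd = fw$grads, bwd = bw$grads,
                    conv = list(W = cv$dW, b = cv$db),
                    dense = list(W = de$dW, b = de$db),
                    bn = list(gamma = bn$dgamma, beta = bn$dbeta)))
}

#' Improved TCN forward pass (evaluation mode)
#'
#' Runs the multiscale forward branch on the sequence, the independent
#' backward branch on the reversed sequence (re-reversed on output), merges
#' the two by elementwise addition, and applies the 1x1 convolution, dense
#' transform, ReLU and per-channel normalization over the sequence. Output
#' at each position depends on the whole sequence.
#'
#' @param x `L x text_width` input matrix.
#' @param model an [init_model()] object (its `tcn` parameters are used).
#' @return `L x tcn_hidden` matrix.
#' @export
improved_tcn <- function(x, model) {
  if (nrow(x) == 0) stop("empty input sequence", call. = FALSE)
  tcn_fwd(x, model$params$tcn, model$cfg, training = FALSE)$out
}

#' Single multiscale branch forward pass (evaluation mode, strictly causal)
#'
#' @param x `L x text_width` input matrix.
#' @param model an [init_model()] object.
#' @param branch `"fwd"` or `"bwd"` parameter set.
#' @return `L x tcn_hidden` matrix.
#' @export
multiscale_forward <- function(x, model, branch = "fwd") {
  ms_fwd(x, model$params$tcn[[branch]], model$cfg, training = FALSE)$out
}

#' Residual block forward pass (evaluation mode)
#'
#' Three causal dilated convolution + ReLU stages plus the residual skip
#' (1x1 projection when the widths differ).
#'
#' @param x input matrix.
#' @param model an [init_model()] object.
#' @param scale_index which scale's block to apply.
#' @param branch `"fwd"` or `"bwd"`.
#' @return `L x channels` matrix.
#' @export
res_block <- function(x, model, scale_index = 1L, branch = "fwd") {
  rb_fwd(x, model$params$tcn[[branch]]$blocks[[scale_index]],
         model$cfg$scales[scale_index], dropout = 0, training = FALSE)$out
}

## ---- BiLSTM ---------------------------------------------------------------

lstm_dir_fwd <- function(x, p) {
  r <- lstm_forward_cpp(x, p$Wx, p$Wh, p$b)
  r$x <- x
  r$p <- p
  r
}

lstm_dir_bwd <- function(cache, dh) {
  g <- lstm_backward_cpp(cache$x, cache$p$Wx, cache$p$Wh, cache$h, cache$c,
                         cache$i, cache$f, cache$o, cache$g, cache$tanh_c, dh)
  list(dx = g$dX, grads = list(Wx = g$dWx, Wh = g$dWh, b = as.numeric(g$db)))
}

bilstm_layer_fwd <- function(x, p) {
  fw <- lstm_dir_fwd(x, p$fwd)
  bw <- lstm_dir_fwd(rev_rows(x), p$bwd)
  list(out = cbind(fw$h, rev_rows(bw$h)), cache = list(fw = fw, bw = bw))
}

bilstm_layer_bwd <- function(cache, dout) {
  H <- ncol(cache$fw$h)
  df <- lstm_dir_bwd(cache$fw, dout[, 1:H, drop = FALSE])
  db <- lstm_dir_bwd(cache$bw, rev_rows(dout[, (H + 1):(2 * H), drop = FALSE]))
  list(dx = df$dx + rev_rows(db$dx),
       grads = list(fwd = df$grads, bwd = db$grads))
}

bilstm_stack_fwd <- function(x, lp, dropout, training) {
  n <- length(lp)
  caches <- vector("list", n)
  h <- x
  for (l in seq_len(n)) {
    ly <- bilstm_layer_fwd(h, lp[[l]])
    dp <- if (l < n) dropout_fwd(ly$out, dropout, training) else
      list(out = ly$out, cache = NULL)
    caches[[l]] <- list(layer = ly$cache, drop = dp$cache)
    h <- dp$out
  }
  list(out = h, cache = caches)
}

bilstm_stack_bwd <- function(cache, dout) {
  n <- length(cache)
  g <- vector("list", n)
  dh <- dout
  for (l in rev(seq_len(n))) {
    dh <- dropout_bwd(cache[[l]]$drop, dh)
    lb <- bilstm_layer_bwd(cache[[l]]$layer, dh)
    g[[l]] <- lb$grads
    dh <- lb$dx
  }
  list(dx = dh, grads = g)
}

#' Stacked BiLSTM forward pass (evaluation mode)
#'
#' Standard LSTM gate recursion (input, forget, output gates and tanh
#' candidate; `h_t = tanh(c_t) * o_t`) run left-to-right and right-to-left
#' with independent parameters, outputs concatenated per position; the
#' configured number of layers is stacked.
#'
#' @param x `L x H` input matrix.
#' @param model an [init_model()] object.
#' @return `L x 2*lstm_hidden` matrix.
#' @export
bilstm <- function(x, model) {
  bilstm_stack_fwd(x, model$params$lstm, dropout = 0, training = FALSE)$out
}

## ---- multi-head attention -------------------------------------------------

mha_fwd <- function(h, ap) {
  n_head <- length(ap$WQ)
  dk <- ncol(ap$WQ[[1]])
  heads <- vector("list", n_head)
  caches <- vector("list", n_head)
  for (j in seq_len(n_head)) {
    Q <- h %*% ap$WQ[[j]]
    K <- h %*% ap$WK[[j]]
    V <- h %*% ap$WV[[j]]
    S <- Q %*% t(K) / sqrt(dk)
    A <- softmax_rows(S)
    heads[[j]] <- A %*% V
    caches[[j]] <- list(Q = Q, K = K, V = V, A = A)
  }
  cat_out <- do.call(cbind, heads)
  out <- cat_out %*% ap$Wo
  list(out = out, cache = list(heads = caches, cat = cat_out, h = h, ap = ap))
}

mha_bwd <- function(cache, dout) {
  ap <- cache$ap
  h <- cache$h
  n_head <- length(ap$WQ)
  dk <- ncol(ap$WQ[[1]])
  dWo <- t(cache$cat) %*% dout
  dcat <- dout %*% t(ap$Wo)
  dh <- matrix(0, nrow(h), ncol(h))
  g <- list(WQ = vector("list", n_head), WK = vector("list", n_head),
            WV = vector("list", n_head), Wo = dWo)
  for (j in seq_len(n_head)) {
    cc <- cache$heads[[j]]
    dOj <- dcat[, ((j - 1) * dk + 1):(j * dk), drop = FALSE]
    dA <- dOj %*% t(cc$V)
    dV <- t(cc$A) %*% dOj
    dS <- softmax_bwd_rows(cc$A, dA)
    dQ <- dS %*% cc$K / sqrt(dk)
    dK <- t(dS) %*% cc$Q / sqrt(dk)
    g$WQ[[j]] <- t(h) %*% dQ
    g$WK[[j]] <- t(h) %*% dK
    g$WV[[j]] <- t(h) %*% dV
    dh <- dh + dQ %*% t(ap$WQ[[j]]) + dK %*% t(ap$WK[[j]]) +
      dV %*% t(ap$WV[[j]])
  }
  list(dx = dh, grads = g)
}

#' Multi-head scaled dot-product self-attention (evaluation mode)
#'
#' Each head projects the input into a `d_k`-dimensional subspace
#' (`d_k = floor(M / heads)`), computes `softmax(Q K' / sqrt(d_k)) V`, and
#' the concatenated heads are mapped back to width M by the output matrix.
#' Every attention weight row sums to 1.
#'
#' @param h `L x M` input matrix (the BiLSTM states; self-attention uses
#'   Q = K = V = h).
#' @param model an [init_model()] object.
#' @param return_weights also return the per-head attention matrices.
#' @return `L x M` matrix, or a list with `out` and `weights`.
#' @export
multi_head_attention <- function(h, model, return_weights = FALSE) {
  r <- mha_fwd(h, model$params$attn)
  if (return_weights) {
    list(out = r$out, weights = lapply(r$cache$heads, `[[`, "A"))
  } else {
    r$out
  }
}

## ---- classifier -----------------------------------------------------------

cls_fwd <- function(hb, ha, cp) {
  z <- cbind(hb, ha)
  cv <- linear_fwd(z, cp$conv$W, cp$conv$b)
  de <- linear_fwd(cv$out, cp$dense$W, cp$dense$b)
  probs <- softmax_rows(de$out)
  list(probs = probs, logits = de$out,
       cache = list(conv = cv$cache, dense = de$cache, wb = ncol(hb)))
}

cls_bwd <- function(cache, dlogits) {
  de <- linear_bwd(cache$dense, dlogits)
  cv <- linear_bwd(cache$conv, de$dx)
  wb <- cache$wb
  list(dhb = cv$dx[, 1:wb, drop = FALSE],
       dha = cv$dx[, (wb + 1):ncol(cv$dx), drop = FALSE],
       grads = list(conv = list(W = cv$dW, b = cv$db),
                    dense = list(W = de$dW, b = de$db)))
}

#' Classifier head (evaluation mode)
#'
#' Concatenates the BiLSTM and attention outputs, fuses them with a 1x1
#' convolution, applies the dense output transform and a row softmax.
#'
#' @param h_bilstm `L x 2W` BiLSTM output.
#' @param h_attn `L x M` attention output.
#' @param model an [init_model()] object.
#' @return `L x K` matrix of class probabilities (rows sum to 1).
#' @export
classify <- function(h_bilstm, h_attn, model) {
  cls_fwd(h_bilstm, h_attn, model$params$cls)$probs
}

## ---- full network ---------------------------------------------------------

nn_fwd <- function(params, X, cfg, training = FALSE) {
  em <- linear_fwd(X, params$embed$W, params$embed$b)
  dp <- dropout_fwd(em$out, cfg$dropout, training)
  tc <- tcn_fwd(dp$out, params$tcn, cfg, training)
  bl <- bilstm_stack_fwd(tc$out, params$lstm, cfg$dropout, training)
  at <- mha_fwd(bl$out, params$attn)
  cl <- cls_fwd(bl$out, at$out, params$cls)
  list(probs = cl$probs, logits = cl$logits,
       cache = list(embed = em$cache, drop = dp$cache, tcn = tc$cache,
                    lstm = bl$cache, attn = at$cache, cls = cl$cache))
}

nn_bwd <- function(cache, dlogits) {
  cl <- cls_bwd(cache$cls, dlogits)
  at <- mha_bwd(cache$attn, cl$dha)
  dbl <- cl$dhb + at$dx
  bl <- bilstm_stack_bwd(cache$lstm, dbl)
  tc <- tcn_bwd(cache$tcn, bl$dx)
  dem <- dropout_bwd(cache$drop, tc$dx)
  em <- linear_bwd(cache$embed, dem)
  list(grads = list(embed = list(W = em$dW, b = em$db),
                    tcn = tc$grads, lstm = bl$grads, attn = at$grads,
                    cls = cl$grads))
}

#' Full forward pass: feature matrix to per-residue class probabilities
#'
#' TextEmbedding projection, improved TCN, stacked BiLSTM, multi-head
#' self-attention, classifier. Evaluation mode: dropout off; the
#' normalization statistics are a function of the input sequence, so
#' repeated calls are identical.
#'
#' @param model an [init_model()] object (or the `model` element of a fit).
#' @param X `L x D` feature matrix from [featurize_record()].
#' @return `L x K` matrix of class probabilities.
#' @export
forward_probs <- function(model, X) {
  if (nrow(X) == 0) stop("empty sequence", call. = FALSE)
  if (ncol(X) != model$feature_dim) {
    stop("feature width ", ncol(X), " does not match the model (",
         model$feature_dim, ")", call. = FALSE)
  }
  nn_fwd(model$params, X, model$cfg, training = FALSE)$probs
}

probs_to_labels <- function(probs, alphabet) {
  paste(alphabet$states[max.col(probs, ties.method = "first")], collapse = "")
}

## ---- parameter-tree utilities --------------------------------------------

tree_leaves <- function(x) {
  if (is.list(x)) unlist(lapply(x, tree_leaves), use.names = FALSE)
  else if (is.null(x)) numeric(0)
  else as.numeric(x)
}

#' Number of trainable parameters
#'
#' @param model an `ssp_model`.
#' @return integer count (batch-norm running statistics excluded).
#' @export
n_parameters <- function(model) {
  count <- function(x, nm = "") {
    if (is.null(x)) return(0L)
    if (is.list(x)) {
      nms <- names(x)
      if (is.null(nms)) nms <- rep("", length(x))
      sum(vapply(seq_along(x), function(i) count(x[[i]], nms[i]), integer(1)))
    } else if (nm %in% c("run_mean", "run_var")) {
      0L
    } else {
      length(x)
    }
  }
  count(model$params)
}

# Elementwise Adam update over mirrored parameter/gradient trees.
# state holds first/second moment trees of the same shape plus step count.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v, nm = "") {
    if (is.null(g) || nm %in% c("run_mean", "run_var")) {
      return(list(p = p, m = m, v = v))
    }
    if (is.list(p)) {
      nms <- names(p)
      if (is.null(nms)) nms <- rep("", length(p))
      if (is.null(m)) m <- vector("list", length(p))
      if (is.null(v)) v <- vector("list", length(p))
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]], nms[i])
        p[i] <- list(r$p); m[i] <- list(r$m); v[i] <- list(r$v)
      }
      return(list(p = p, m = m, v = v))
    }
    if (is.null(m)) m <- p * 0
    if (is.null(v)) v <- p * 0
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  state$m <- r$m
  state$v <- r$v
  list(params = r$p, state = state)
}

# `x[i] <- list(v)` (not `[[<-`) keeps NULL leaves in place.
tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (i in seq_along(a)) a[i] <- list(tree_add(a[[i]], b[[i]]))
    a
  } else {
    a + b
  }
}

tree_scale <- function(a, s) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    for (i in seq_along(a)) a[i] <- list(tree_scale(a[[i]], s))
    a
  } else {
    a * s
  }
}
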