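#' Train skip-gram residue embeddings
#'
#' Word2vec-style skip-gram with negative sampling over overlapping k-mer
#' tokens of the sequence corpus. With the default `k = 1` every token is a
#' single residue, so embeddings stay positionally aligned with the sequence.
#' Training is mini-batched stochastic gradient descent; the noise
#' distribution is the unigram distribution raised to the 3/4 power, as in
#' the original algorithm. The result is fully reproducible from the seed.
#'
#' @param corpus character vector of residue strings.
#' @param k k-mer size (tokens are overlapping k-mers).
#' @param window one-sided context window in tokens.
#' @param dim embedding dimension.
#' @param epochs passes over the corpus.
#' @param negative negative samples per (center, context) pair.
#' @param lr SGD learning rate.
#' @param seed integer seed.
#' @return an `embedding_model`: list with `vectors` (vocab x dim matrix with
#'   token rownames), `k`, and the training hyperparameters.
#' @export
train_embeddings <- function(corpus, k = 1L, window = 5L, dim = 16L,
                             epochs = 20L, negative = 5L, lr = 0.05,
                             seed = 1L) {
  if (length(corpus) == 0) stop("empty corpus", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  toks <- lapply(corpus, tokenize_kmers, k = k)
  toks <- toks[lengths(toks) > 0]
  if (length(toks) == 0) {
    stop("every corpus sequence is shorter than k = ", k, call. = FALSE)
  }
  all_tok <- unlist(toks)
  vocab <- sort(unique(all_tok))
  counts <- table(factor(all_tok, levels = vocab))
  noise <- as.numeric(counts)^0.75
  noise <- noise / sum(noise)

  # (center, context) index pairs, fixed for all epochs
  pair_c <- integer(0); pair_o <- integer(0)
  for (tk in toks) {
    ti <- match(tk, vocab)
    n <- length(ti)
    for (off in seq_len(min(window, n - 1))) {
      pair_c <- c(pair_c, ti[1:(n - off)], ti[(1 + off):n])
      pair_o <- c(pair_o, ti[(1 + off):n], ti[1:(n - off)])
    }
  }

  V <- length(vocab)
  with_local_seed(seed, {
    W <- matrix(stats::runif(V * dim, -0.5, 0.5) / dim, V, dim)
    C <- matrix(0, V, dim)
    n_pairs <- length(pair_c)
    chunk <- 512L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_pairs)
      if (n_pairs > 0) {
        starts <- seq(1L, n_pairs, by = chunk)
        for (s0 in starts) {
          idx <- ord[s0:min(s0 + chunk - 1L, n_pairs)]
          cen <- pair_c[idx]; ctx <- pair_o[idx]
          m <- length(idx)
          negs <- matrix(sample.int(V, m * negative, replace = TRUE,
                                    prob = noise), m, negative)
          Vc <- W[cen, , drop = FALSE]
          dV <- matrix(0, m, dim)
          tgt_idx <- c(ctx, as.vector(negs))
          lab <- c(rep(1, m), rep(0, m * negative))
          Tm <- C[tgt_idx, , drop = FALSE]
          Vrep <- Vc[rep(seq_len(m), 1 + negative), , drop = FALSE]
          sc <- 1 / (1 + exp(-rowSums(Vrep * Tm)))
          g <- lr * (lab - sc)
          dV <- rowsum(g * Tm, rep(seq_len(m), 1 + negative))
          dT <- g * Vrep
          # average (not sum) the per-token contributions within the chunk:
          # with a small vocabulary a token recurs many times per chunk and
          # summed steps diverge
          W_upd <- rowsum(dV, cen)
          W_cnt <- as.vector(rowsum(rep(1, m), cen))
          wi <- as.integer(rownames(W_upd))
          W[wi, ] <- W[wi, , drop = FALSE] + W_upd / W_cnt
          C_upd <- rowsum(dT, tgt_idx)
          C_cnt <- as.vector(rowsum(rep(1, length(tgt_idx)), tgt_idx))
          ci <- as.integer(rownames(C_upd))
          C[ci, ] <- C[ci, , drop = FALSE] + C_upd / C_cnt
        }
      }
    }
    rownames(W) <- vocab
    structure(list(vectors = W, k = as.integer(k), window = as.integer(window),
                   dim = as.integer(dim), epochs = as.integer(epochs),
                   negative = as.integer(negative), lr = lr,
                   seed = as.integer(seed)),
              class = "embedding_model")
  })
}

tokenize_kmers <- function(sequence, k) {
  L <- nchar(sequence)
  if (L < k) return(character(0))
  substring(sequence, 1:(L - k + 1), k:L)
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model: %d tokens (k=%d), dim %d>\n",
              nrow(x$vectors), x$k, x$dim))
  invisible(x)
}

#' Embed a residue string with a trained model
#'
#' Each overlapping k-mer's vector is assigned to the k-mer's first residue
#' position; out-of-vocabulary tokens (and trailing positions with no k-mer,
#' when `k > 1`) get the zero vector.
#'
#' @param model an [train_embeddings()] model.
#' @param sequence residue string.
#' @return `L x dim` numeric matrix.
#' @export
embed_sequence <- function(model, sequence) {
  L <- nchar(sequence)
  out <- matrix(0, L, model$dim)
  toks <- tokenize_kmers(sequence, model$k)
  if (length(toks) == 0) return(out)
  idx <- match(toks, rownames(model$vectors))
  hit <- !is.na(idx)
  out[which(hit), ] <- model$vectors[idx[hit], , drop = FALSE]
  out
}

#' Persist / restore an embedding model as plain text
#'
#' Writes `<prefix>.vec` (one line per token: token then `dim` floats) and a
#' JSON sidecar `<prefix>.json` with the hyperparameters.
#'
#' @param model embedding model.
#' @param prefix path prefix (no extension).
#' @return `prefix`, invisibly.
#' @export
write_embeddings <- function(model, prefix) {
  vec_lines <- vapply(seq_len(nrow(model$vectors)), function(i) {
    paste(c(rownames(model$vectors)[i],
            format(model$vectors[i, ], digits = 17)), collapse = " ")
  }, character(1))
  writeLines(vec_lines, paste0(prefix, ".vec"))
  meta <- model[setdiff(names(model), "vectors")]
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(prefix) {
  lines <- readLines(paste0(prefix, ".vec"))
  parts <- strsplit(lines, " +")
  toks <- vapply(parts, `[`, character(1), 1)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]),
                   numeric(length(parts[[1]]) - 1)))
  rownames(vecs) <- toks
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  structure(c(list(vectors = vecs), meta), class = "embedding_model")
}
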