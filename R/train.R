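#' Train the secondary-structure predictor
#'
#' Mini-batch Adam on the blended loss
#' `(1 - alpha) * cross_entropy + alpha * kd_loss` (the soft term only when
#' `cfg$distill` is on and teacher logits are supplied). Skip-gram embeddings
#' are trained on the training sequences unless a prebuilt model is passed.
#' Sequences are processed whole (variable length, one gradient per chain,
#' averaged over the batch), so no padding or masking is needed. The run is
#' fully determined by `cfg$seed`.
#'
#' @param train_records labeled record tibble.
#' @param val_records optional labeled tibble monitored for early stopping
#'   and checkpoint selection.
#' @param cfg a [model_config()].
#' @param teacher optional `teacher_logits` (required when `cfg$distill`).
#' @param emb optional prebuilt [train_embeddings()] model.
#' @param verbose print per-epoch progress.
#' @return an `ssp_fit`: list with `model` (best parameters), `emb`,
#'   `history` tibble, `cfg`, `best_epoch`, `wall_time`.
#' @export
train <- function(train_records, val_records = NULL, cfg = model_config(),
                  teacher = NULL, emb = NULL, verbose = FALSE) {
  t0 <- Sys.time()
  ab <- cfg_alphabet(cfg)
  col <- if (cfg$alphabet == "Q8") "labels8" else "labels3"
  if (any(is.na(train_records[[col]]))) {
    stop("training records must all carry ", cfg$alphabet, " labels",
         call. = FALSE)
  }
  if (cfg$distill) {
    if (is.null(teacher)) {
      stop("cfg$distill is on but no teacher logits were supplied",
           call. = FALSE)
    }
    missing <- setdiff(train_records$id, names(teacher))
    if (length(missing) > 0) {
      stop("teacher logits missing for record '", missing[1], "'",
           call. = FALSE)
    }
  }
  if (is.null(emb)) {
    emb <- train_embeddings(train_records$sequence, k = cfg$k,
                            window = cfg$w2v_window, dim = cfg$embed_dim,
                            epochs = cfg$w2v_epochs,
                            negative = cfg$w2v_negative, seed = cfg$seed)
  }
  feats <- featurize_records(train_records, emb)
  X <- feats$features
  y_idx <- lapply(train_records[[col]], label_indices, alphabet = ab)
  val_X <- NULL
  if (!is.null(val_records)) {
    val_X <- featurize_records(val_records, emb)$features
  }
  model <- init_model(cfg, ncol(X[[1]]))
  params <- model$params
  K <- length(ab)
  n <- length(X)
  state <- list(m = NULL, v = NULL, t = 0L)
  history <- vector("list", cfg$epochs)
  best <- list(metric = -Inf, params = params, epoch = 0L)
  bad_epochs <- 0L

  eval_acc <- function(params, feats_list, recs) {
    hits <- 0L; tot <- 0L
    for (i in seq_along(feats_list)) {
      pr <- nn_fwd(params, feats_list[[i]], cfg, training = FALSE)$probs
      pred <- max.col(pr, ties.method = "first")
      obs <- label_indices(recs[[col]][i], ab)
      hits <- hits + sum(pred == obs)
      tot <- tot + length(obs)
    }
    100 * hits / tot
  }

  with_local_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      b0 <- 1L
      while (b0 <= n) {
        batch <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        b0 <- b0 + cfg$batch_size
        grads <- NULL
        for (i in batch) {
          fw <- nn_fwd(params, X[[i]], cfg, training = TRUE)
          L <- length(y_idx[[i]])
          yi <- matrix(0, L, K)
          yi[cbind(seq_len(L), y_idx[[i]])] <- 1
          zt <- if (cfg$distill) teacher[[train_records$id[i]]] else NULL
          w_hard <- if (!is.null(zt)) 1 - cfg$alpha else 1
          dlogits <- w_hard * (fw$probs - yi) / L
          loss <- w_hard * hard_loss(fw$probs, train_records[[col]][i], ab)
          if (!is.null(zt)) {
            loss <- loss + cfg$alpha *
              kd_loss(fw$logits, zt, cfg$rho, cfg$kd_rho2_scale)
            dlogits <- dlogits + cfg$alpha *
              kd_loss_grad(fw$logits, zt, cfg$rho, cfg$kd_rho2_scale)
          }
          ep_loss <- ep_loss + loss
          g <- nn_bwd(fw$cache, dlogits)$grads
          grads <- if (is.null(grads)) g else tree_add(grads, g)
        }
        grads <- tree_scale(grads, 1 / length(batch))
        upd <- adam_step(params, grads, state, cfg$lr)
        params <- upd$params
        state <- upd$state
      }
      tr_acc <- eval_acc(params, X, train_records)
      va_acc <- if (is.null(val_records)) NA_real_ else
        eval_acc(params, val_X, val_records)
      history[[ep]] <- tibble::tibble(
        epoch = ep, train_loss = ep_loss / n, train_accuracy = tr_acc,
        val_accuracy = va_acc
      )
      monitor <- if (is.null(val_records)) tr_acc else va_acc
      if (monitor > best$metric) {
        best <- list(metric = monitor, params = params, epoch = ep)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
      }
      if (verbose) {
        message(sprintf("epoch %3d | loss %.4f | train %.1f%%%s", ep,
                        ep_loss / n, tr_acc,
                        if (is.na(va_acc)) "" else
                          sprintf(" | val %.1f%%", va_acc)))
      }
      if (bad_epochs >= cfg$patience) break
    }
  })
  model$params <- best$params
  structure(list(model = model, emb = emb,
                 history = dplyr::bind_rows(history),
                 cfg = cfg, best_epoch = best$epoch,
                 wall_time = as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs"))),
            class = "ssp_fit")
}

#' @export
print.ssp_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<ssp_fit %s: %d epochs (best %d), final train acc %.1f%%, %d params, %.1fs>\n",
    x$cfg$alphabet, nrow(h), x$best_epoch,
    h$train_accuracy[nrow(h)], n_parameters(x$model), x$wall_time))
  invisible(x)
}

#' Per-record probability matrices for a fitted model
#'
#' @param fit an `ssp_fit`.
#' @param records record tibble.
#' @return named list id -> `L x K` probability matrix, with argmax label
#'   strings attached as the `labels` attribute.
#' @export
predict_probs <- function(fit, records) {
  ab <- cfg_alphabet(fit$cfg)
  feats <- featurize_records(records, fit$emb)
  probs <- lapply(feats$features, forward_probs, model = fit$model)
  names(probs) <- feats$id
  labels <- vapply(probs, probs_to_labels, character(1), alphabet = ab)
  attr(probs, "labels") <- labels
  probs
}

#' Predict per-residue secondary structure
#'
#' @param object an `ssp_fit`.
#' @param records record tibble to predict.
#' @param ... unused.
#' @return tibble with one row per residue: `id`, `position` (1-based),
#'   `residue`, one probability column per state (`p_H`, ...), and the
#'   argmax `label`.
#' @export
predict.ssp_fit <- function(object, records, ...) {
  ab <- cfg_alphabet(object$cfg)
  probs <- predict_probs(object, records)
  labels <- attr(probs, "labels")
  rows <- lapply(seq_len(nrow(records)), function(i) {
    id <- records$id[i]
    p <- probs[[id]]
    colnames(p) <- paste0("p_", ab$states)
    dplyr::bind_cols(
      tibble::tibble(
        id = id, position = seq_len(nrow(p)),
        residue = strsplit(records$sequence[i], "", fixed = TRUE)[[1]]
      ),
      tibble::as_tibble(p),
      tibble::tibble(label = strsplit(labels[[id]], "", fixed = TRUE)[[1]])
    )
  })
  dplyr::bind_rows(rows)
}

#' Evaluate a fitted model on labeled records
#'
#' Convenience wrapper: predict then [evaluate()].
#'
#' @param fit an `ssp_fit`.
#' @param records labeled record tibble.
#' @param ... passed to [evaluate()].
#' @return a `metrics_report`.
#' @export
evaluate_fit <- function(fit, records, ...) {
  probs <- predict_probs(fit, records)
  evaluate(records, probs, cfg_alphabet(fit$cfg), ...)
}

## ---- checkpointing --------------------------------------------------------

params_flatten <- function(p) {
  unlist(lapply(p, function(x) {
    if (is.list(x)) params_flatten(x) else if (is.null(x)) numeric(0) else
      as.numeric(x)
  }), use.names = FALSE)
}

params_unflatten <- function(template, vec) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) {
      for (i in seq_along(x)) x[i] <- list(fill(x[[i]]))
      x
    } else if (is.null(x)) {
      NULL
    } else {
      n <- length(x)
      out <- vec[(pos + 1L):(pos + n)]
      pos <<- pos + n
      if (is.matrix(x)) out <- matrix(out, nrow(x), ncol(x))
      out
    }
  }
  out <- fill(template)
  stopifnot(pos == length(vec))
  out
}

#' Save / load a fitted model as a JSON checkpoint
#'
#' The checkpoint stores the resolved configuration, the embedding model and
#' the flattened parameter vector, which together reproduce predictions
#' exactly.
#'
#' @param fit an `ssp_fit`.
#' @param path output `.json` path.
#' @return `path` (`save_checkpoint`) or the restored `ssp_fit`
#'   (`load_checkpoint`), invisibly for the writer.
#' @export
save_checkpoint <- function(fit, path) {
  cfg <- fit$cfg
  obj <- list(
    version = 1L,
    cfg = cfg[setdiff(names(cfg), NULL)],
    feature_dim = fit$model$feature_dim,
    params = params_flatten(fit$model$params),
    emb = list(tokens = rownames(fit$emb$vectors),
               vectors = as.numeric(fit$emb$vectors),
               k = fit$emb$k, window = fit$emb$window, dim = fit$emb$dim,
               epochs = fit$emb$epochs, negative = fit$emb$negative,
               lr = fit$emb$lr, seed = fit$emb$seed),
    best_epoch = fit$best_epoch
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$version) || obj$version != 1L) {
    stop("unsupported checkpoint version", call. = FALSE)
  }
  cfg <- do.call(model_config, obj$cfg[names(formals(model_config))[
    names(formals(model_config)) %in% names(obj$cfg)]])
  model <- init_model(cfg, obj$feature_dim)
  model$params <- params_unflatten(model$params, obj$params)
  vecs <- matrix(obj$emb$vectors, nrow = length(obj$emb$tokens))
  rownames(vecs) <- obj$emb$tokens
  emb <- structure(list(vectors = vecs, k = obj$emb$k,
                        window = obj$emb$window, dim = obj$emb$dim,
                        epochs = obj$emb$epochs, negative = obj$emb$negative,
                        lr = obj$emb$lr, seed = obj$emb$seed),
                   class = "embedding_model")
  structure(list(model = model, emb = emb, history = tibble::tibble(),
                 cfg = cfg, best_epoch = obj$best_epoch, wall_time = NA_real_),
            class = "ssp_fit")
}

## ---- parameter sweep ------------------------------------------------------

#' Sensitivity sweep over dilation-scale lists and distillation weights
#'
#' Trains one model per grid cell (typically at reduced epochs) and records
#' the test accuracy, reproducing the scale/alpha sensitivity surface.
#'
#' @param train_records,test_records labeled record tibbles.
#' @param scales_grid list of dilation vectors, e.g.
#'   `list(1, c(1, 9), c(1, 9, 81))`.
#' @param alphas numeric vector of distillation blend weights.
#' @param cfg base [model_config()]; each cell overrides `scales`, `alpha`
#'   (and turns distillation on for `alpha > 0`, off otherwise).
#' @param teacher `teacher_logits` used whenever a cell distills.
#' @param verbose print progress.
#' @return tibble with columns `scales`, `alpha`, `seed`, `accuracy`,
#'   `sov99`.
#' @export
sweep_scales_alpha <- function(train_records, test_records, scales_grid,
                               alphas, cfg = model_config(), teacher = NULL,
                               verbose = FALSE) {
  if (length(scales_grid) == 0 || length(alphas) == 0) {
    stop("empty sweep grid", call. = FALSE)
  }
  emb <- train_embeddings(train_records$sequence, k = cfg$k,
                          window = cfg$w2v_window, dim = cfg$embed_dim,
                          epochs = cfg$w2v_epochs,
                          negative = cfg$w2v_negative, seed = cfg$seed)
  rows <- list()
  for (sc in scales_grid) {
    for (a in alphas) {
      cell <- cfg
      cell$scales <- sc
      cell$alpha <- a
      cell$distill <- a > 0 && !is.null(teacher)
      fit <- train(train_records, cfg = cell,
                   teacher = if (cell$distill) teacher else NULL, emb = emb)
      rep <- evaluate_fit(fit, test_records)
      rows[[length(rows) + 1]] <- tibble::tibble(
        scales = paste(sc, collapse = ","), alpha = a, seed = cfg$seed,
        accuracy = rep$summary$accuracy, sov99 = rep$summary$sov99
      )
      if (verbose) {
        message(sprintf("scales [%s], alpha %.1f -> ACC %.1f%%",
                        paste(sc, collapse = ","), a,
                        rep$summary$accuracy))
      }
    }
  }
  dplyr::bind_rows(rows)
}
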