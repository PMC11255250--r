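#' Run-length segmentation of a label string
#'
#' Decomposes a label string into its maximal constant runs, the substrate of
#' the SOV99 score.
#'
#' @param labels label string.
#' @return tibble with columns `state`, `start` (0-based inclusive), `end`
#'   (0-based exclusive); concatenating the runs reproduces the input.
#' @export
segments <- function(labels) {
  if (nchar(labels) == 0) {
    return(tibble::tibble(state = character(), start = integer(),
                          end = integer()))
  }
  ch <- strsplit(labels, "", fixed = TRUE)[[1]]
  r <- rle(ch)
  end <- cumsum(r$lengths)
  tibble::tibble(state = r$values, start = as.integer(end - r$lengths),
                 end = as.integer(end))
}

#' SOV99 segment-overlap score
#'
#' Zemla-style segment overlap between an observed (reference) and a
#' predicted secondary-structure assignment. For every conformational state,
#' each pair of overlapping observed/predicted segments `(s1, s2)` (the
#' observed segment is `s1`) contributes
#' `(minov + delta) / maxov * len(s1)`, where `minov` is the actual overlap,
#' `maxov` the total extent covered by either segment, and the boundary
#' tolerance `delta = min(maxov - minov, minov, len(s1) %/% 2, len(s2) %/% 2)`
#' is capped at half the shorter segment. The normalizer sums `len(s1)` over
#' all overlapping pairs plus all observed segments with no overlapping
#' partner, which confines the score to `[0, 100]`. An observed segment
#' overlapping several predicted segments contributes once per pair to both
#' the numerator and the normalizer.
#'
#' @param observed,predicted label strings of equal length.
#' @param alphabet alphabet both strings are validated against.
#' @return percentage in `[0, 100]`; 0 (with a warning) when the observed
#'   string is empty.
#' @examples
#' sov99("HHHHHHCC", "HHHCCCCC", q3_alphabet())  # 65
#' @export
sov99 <- function(observed, predicted, alphabet = q3_alphabet()) {
  if (nchar(observed) != nchar(predicted)) {
    stop("observed and predicted lengths differ", call. = FALSE)
  }
  validate_labels(observed, alphabet, "<observed>")
  validate_labels(predicted, alphabet, "<predicted>")
  obs <- segments(observed)
  prd <- segments(predicted)
  num <- 0
  N <- 0
  for (i in seq_len(nrow(obs))) {
    st <- obs$state[i]
    s1s <- obs$start[i]; s1e <- obs$end[i]
    len1 <- s1e - s1s
    partners <- which(prd$state == st & prd$start < s1e & prd$end > s1s)
    if (length(partners) == 0) {
      N <- N + len1  # unmatched observed segment, S'(i)
      next
    }
    for (j in partners) {
      s2s <- prd$start[j]; s2e <- prd$end[j]
      len2 <- s2e - s2s
      minov <- min(s1e, s2e) - max(s1s, s2s)
      maxov <- max(s1e, s2e) - min(s1s, s2s)
      delta <- min(maxov - minov, minov, len1 %/% 2, len2 %/% 2)
      num <- num + (minov + delta) / maxov * len1
      N <- N + len1
    }
  }
  if (N == 0) {
    warning("no observed segments; SOV99 defined as 0", call. = FALSE)
    return(0)
  }
  100 * num / N
}

#' Per-residue accuracy (Q3/Q8)
#'
#' Percentage of positions where the predicted state equals the observed
#' state. The per-state correct counts `S_i` are attached as the `counts`
#' attribute.
#'
#' @param observed,predicted label strings of equal length.
#' @return percentage in `[0, 100]` with attribute `counts` (named vector of
#'   correct residues per observed state).
#' @export
accuracy <- function(observed, predicted) {
  L <- nchar(observed)
  if (L != nchar(predicted)) {
    stop("observed and predicted lengths differ", call. = FALSE)
  }
  if (L == 0) stop("empty label strings", call. = FALSE)
  o <- strsplit(observed, "", fixed = TRUE)[[1]]
  p <- strsplit(predicted, "", fixed = TRUE)[[1]]
  hit <- o == p
  counts <- tapply(hit, o, sum)
  structure(100 * sum(hit) / L,
            counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Micro-averaged one-vs-rest multiclass AUC
#'
#' Pools every (position, class) decision: each of the `L x K` scores is
#' paired with a 0/1 indicator of whether that class is the observed one at
#' that position, the pooled ROC curve is traced by sweeping a threshold
#' over the scores (micro-averaged TPR against FPR), and the area is
#' computed by the trapezoidal rule — equivalent to counting tied
#' positive/negative score pairs as one half.
#'
#' @param observed label string.
#' @param scores `L x K` matrix of class scores (columns in alphabet order).
#' @param alphabet state alphabet.
#' @return AUC in `[0, 1]`.
#' @export
miauc <- function(observed, scores, alphabet = q3_alphabet()) {
  if (!all(is.finite(scores))) stop("non-finite scores", call. = FALSE)
  idx <- label_indices(observed, alphabet)
  if (length(idx) != nrow(scores)) {
    stop("label length != score rows", call. = FALSE)
  }
  y <- matrix(0, nrow(scores), ncol(scores))
  y[cbind(seq_along(idx), idx)] <- 1
  micro_auc(as.vector(y), as.vector(scores))
}

# Trapezoidal ROC AUC over a pooled binary problem; ties grouped.
micro_auc <- function(y, s) {
  P <- sum(y == 1)
  Nn <- sum(y == 0)
  if (P == 0 || Nn == 0) {
    stop("need both positive and negative pooled decisions", call. = FALSE)
  }
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]; s <- s[ord]
  grp <- cumsum(!duplicated(s))  # threshold groups (distinct scores)
  tp <- tapply(y == 1, grp, sum)
  fp <- tapply(y == 0, grp, sum)
  tpr <- c(0, cumsum(tp) / P)
  fpr <- c(0, cumsum(fp) / Nn)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Evaluate predictions against labeled records
#'
#' Computes per-record accuracy, SOV99 (on the argmax label strings) and
#' micro-averaged AUC, and pools them across records: accuracy and MiAUC
#' over all residues, SOV99 as the residue-length-weighted mean of the
#' per-chain scores (or over the concatenated strings with
#' `sov_pooling = "concatenate"`).
#'
#' @param records labeled record tibble.
#' @param predictions named list id -> `L x K` probability matrix.
#' @param alphabet state alphabet the labels and matrix columns follow.
#' @param sov_pooling `"length_weighted"` or `"concatenate"`.
#' @return a `metrics_report`: list with tibbles `per_record` and `summary`.
#' @export
evaluate <- function(records, predictions, alphabet = q3_alphabet(),
                     sov_pooling = c("length_weighted", "concatenate")) {
  sov_pooling <- match.arg(sov_pooling)
  col <- if (length(alphabet) == 8) "labels8" else "labels3"
  missing <- setdiff(records$id, names(predictions))
  if (length(missing) > 0) {
    stop("missing prediction for record '", missing[1], "'", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    id <- records$id[i]
    obs <- records[[col]][i]
    if (is.na(obs)) stop("record '", id, "' has no ", alphabet$name,
                         " labels", call. = FALSE)
    probs <- predictions[[id]]
    pred <- probs_to_labels(probs, alphabet)
    tibble::tibble(
      id = id, length = nchar(obs),
      accuracy = as.numeric(accuracy(obs, pred)),
      sov99 = sov99(obs, pred, alphabet),
      miauc = miauc(obs, probs, alphabet),
      observed = obs, predicted = pred
    )
  })
  per_record <- dplyr::bind_rows(rows)
  all_obs <- paste(per_record$observed, collapse = "")
  all_pred <- paste(per_record$predicted, collapse = "")
  all_probs <- do.call(rbind, unname(predictions[records$id]))
  pooled_sov <- if (sov_pooling == "concatenate") {
    sov99(all_obs, all_pred, alphabet)
  } else {
    sum(per_record$sov99 * per_record$length) / sum(per_record$length)
  }
  summary <- tibble::tibble(
    n_records = nrow(per_record),
    n_residues = sum(per_record$length),
    accuracy = as.numeric(accuracy(all_obs, all_pred)),
    sov99 = pooled_sov,
    miauc = miauc(all_obs, all_probs, alphabet),
    alphabet = alphabet$name
  )
  structure(list(per_record = per_record, summary = summary),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<metrics_report: %d records, %d residues | ACC %.1f%%, SOV99 %.1f, MiAUC %.4f (%s)>\n",
    s$n_records, s$n_residues, s$accuracy, s$sov99, s$miauc, s$alphabet))
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Writes `metrics.json` (summary + per-record values) and `metrics.csv`
#' (one row per record plus a summary row).
#'
#' @param report a [evaluate()] report.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_metrics <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  per_rec <- report$per_record[, c("id", "length", "accuracy", "sov99",
                                   "miauc")]
  jsonlite::write_json(
    list(summary = as.list(report$summary), per_record = per_rec),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA
  )
  csv <- rbind(
    data.frame(id = per_rec$id, length = per_rec$length,
               accuracy = per_rec$accuracy, sov99 = per_rec$sov99,
               miauc = per_rec$miauc),
    data.frame(id = "<summary>", length = report$summary$n_residues,
               accuracy = report$summary$accuracy,
               sov99 = report$summary$sov99,
               miauc = report$summary$miauc)
  )
  utils::write.csv(csv, file.path(dir, "metrics.csv"), row.names = FALSE)
  invisible(dir)
}
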