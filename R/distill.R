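#' Temperature-softened softmax
#'
#' `soften(z, rho) = softmax(z / rho)`. Larger temperatures flatten the
#' distribution, amplifying the relative weight of non-argmax ("negative")
#' classes — the mechanism by which a distilled student sees more of the
#' teacher's dark knowledge than the hard argmax label carries.
#'
#' @param z numeric vector of class scores, or an `L x K` matrix (softened
#'   row-wise).
#' @param rho positive temperature.
#' @return probability vector/matrix; rows sum to 1.
#' @export
soften <- function(z, rho = 1) {
  if (rho <= 0) stop("temperature rho must be positive", call. = FALSE)
  if (is.matrix(z)) softmax_rows(z / rho) else
    as.numeric(softmax_rows(matrix(z / rho, nrow = 1)))
}

#' Knowledge-distillation loss
#'
#' Mean over positions of `KL(teacher || student)` between the
#' temperature-softened distributions, multiplied by `rho^2` (the classic
#' gradient-scale convention making the soft-gradient magnitude
#' temperature-invariant; disable via `rho2_scale`). Zero exactly when the
#' softened distributions agree.
#'
#' @param z_student,z_teacher `L x K` logit matrices (same shape).
#' @param rho temperature.
#' @param rho2_scale multiply by `rho^2`.
#' @return nonnegative scalar (nats).
#' @export
kd_loss <- function(z_student, z_teacher, rho = 2, rho2_scale = TRUE) {
  if (!all(dim(z_student) == dim(z_teacher))) {
    stop("student and teacher logit shapes differ", call. = FALSE)
  }
  ps <- soften(z_student, rho)
  pt <- soften(z_teacher, rho)
  kl <- rowSums(pt * (log(pt + 1e-12) - log(ps + 1e-12)))
  out <- mean(kl)
  if (rho2_scale) out <- out * rho^2
  out
}

# Gradient of kd_loss with respect to the student logits.
kd_loss_grad <- function(z_student, z_teacher, rho = 2, rho2_scale = TRUE) {
  ps <- soften(z_student, rho)
  pt <- soften(z_teacher, rho)
  g <- (ps - pt) / (rho * nrow(z_student))
  if (rho2_scale) g <- g * rho^2
  g
}

#' Hard cross-entropy loss over a label string
#'
#' Mean over positions of `-log p[true class]`.
#'
#' @param probs `L x K` probability matrix.
#' @param labels label string of length L.
#' @param alphabet state alphabet matching the probability columns.
#' @return scalar loss (nats).
#' @export
hard_loss <- function(probs, labels, alphabet) {
  idx <- label_indices(labels, alphabet)
  if (length(idx) != nrow(probs)) {
    stop("label length ", length(idx), " != probability rows ", nrow(probs),
         call. = FALSE)
  }
  -mean(log(probs[cbind(seq_along(idx), idx)] + 1e-12))
}

label_indices <- function(labels, alphabet) {
  ch <- strsplit(labels, "", fixed = TRUE)[[1]]
  idx <- unname(alphabet$index_of[ch])
  if (anyNA(idx)) stop("label outside alphabet", call. = FALSE)
  idx
}

#' Blended training loss
#'
#' `(1 - alpha) * cross_entropy + alpha * kd_loss`; `alpha = 0` recovers
#' plain hard-label training exactly, `alpha = 1` trains on the teacher
#' alone. When no teacher logits are available the hard loss is returned and
#' a notice is emitted.
#'
#' @param probs_student `L x K` probability matrix (for the hard term).
#' @param labels label string.
#' @param z_student,z_teacher `L x K` logit matrices (for the soft term);
#'   `z_teacher = NULL` falls back to the pure hard loss.
#' @param alphabet state alphabet.
#' @param alpha blend weight in `[0, 1]`.
#' @param rho temperature.
#' @param rho2_scale see [kd_loss()].
#' @return scalar loss.
#' @export
total_loss <- function(probs_student, labels, z_student = NULL,
                       z_teacher = NULL, alphabet = q3_alphabet(),
                       alpha = 0.2, rho = 2, rho2_scale = TRUE) {
  hard <- hard_loss(probs_student, labels, alphabet)
  if (alpha == 0) return(hard)
  if (is.null(z_teacher)) {
    message("no teacher logits for this record; using the hard loss only")
    return(hard)
  }
  soft <- kd_loss(z_student, z_teacher, rho, rho2_scale)
  (1 - alpha) * hard + alpha * soft
}

#' Read cached teacher logits
#'
#' JSON-lines format: an optional header object `{"classes": [...]}`
#' declaring the class order, then one object `{"id": ..., "logits": [[...]]}`
#' per record. A directory of per-record TSV matrices (`<id>.tsv`, one row
#' per residue, one column per class) is also accepted.
#'
#' @param path file (JSON-lines) or directory (TSV matrices).
#' @param alphabet state alphabet; the class count and any declared class
#'   order are validated against it.
#' @param records optional record tibble; when given, every teacher matrix
#'   must match its record's sequence length.
#' @return named list id -> `L x K` logit matrix, class `teacher_logits`.
#' @export
read_teacher_logits <- function(path, alphabet = q3_alphabet(),
                                records = NULL) {
  K <- length(alphabet)
  out <- list()
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tsv$", full.names = TRUE)
    for (f in files) {
      id <- sub("\\.tsv$", "", basename(f))
      m <- as.matrix(utils::read.table(f, sep = "\t"))
      dimnames(m) <- NULL
      if (ncol(m) != K) {
        stop(sprintf("teacher matrix '%s' has %d classes; alphabet %s has %d",
                     id, ncol(m), alphabet$name, K), call. = FALSE)
      }
      out[[id]] <- m
    }
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    for (ln in lines) {
      obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
      if (!is.null(obj$classes)) {
        if (!identical(as.character(obj$classes), alphabet$states)) {
          stop("teacher class order (", paste(obj$classes, collapse = ""),
               ") does not match the ", alphabet$name, " alphabet",
               call. = FALSE)
        }
        next
      }
      if (is.null(obj$id) || is.null(obj$logits)) {
        stop("teacher logits line lacks 'id'/'logits'", call. = FALSE)
      }
      if (obj$id %in% names(out)) {
        stop("duplicate teacher id: ", obj$id, call. = FALSE)
      }
      m <- obj$logits
      if (is.null(dim(m))) m <- matrix(m, nrow = 1)
      if (ncol(m) != K) {
        stop(sprintf("teacher record '%s' has %d classes; alphabet %s has %d",
                     obj$id, ncol(m), alphabet$name, K), call. = FALSE)
      }
      out[[obj$id]] <- unname(as.matrix(m))
    }
  }
  if (!is.null(records)) {
    for (id in intersect(names(out), records$id)) {
      L <- nchar(records$sequence[records$id == id][1])
      if (nrow(out[[id]]) != L) {
        stop(sprintf(
          "teacher logits for '%s' have %d rows but the sequence has %d residues",
          id, nrow(out[[id]]), L), call. = FALSE)
      }
    }
  }
  structure(out, class = "teacher_logits", alphabet = alphabet$name)
}

#' Write teacher logits as JSON-lines
#'
#' @param teacher named list id -> logit matrix.
#' @param path output path.
#' @param alphabet state alphabet (written as the header's class order).
#' @return `path`, invisibly.
#' @export
write_teacher_logits <- function(teacher, path, alphabet = q3_alphabet()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(classes = alphabet$states),
                              auto_unbox = TRUE, digits = NA), con)
  for (id in names(teacher)) {
    writeLines(jsonlite::toJSON(
      list(id = id, logits = teacher[[id]]), auto_unbox = TRUE, digits = NA
    ), con)
  }
  invisible(path)
}
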