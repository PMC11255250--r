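AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Construct a table of protein records
#'
#' A protein record couples a sequence with optional per-residue secondary
#' structure labels. Records are kept as one row per protein in a tibble so
#' they compose with dplyr verbs; `labels3` is derived from `labels8` via
#' [reduce_to_q3()] when only the 8-state labels are given.
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of residue strings over the 20 canonical
#'   amino-acid letters plus `X` for unknown; lower case is folded to upper.
#' @param labels8,labels3 optional label strings (8-state / 3-state); when
#'   present each must have the same length as its sequence.
#' @return a tibble with columns `id`, `sequence`, `labels8`, `labels3`.
#' @export
protein_records <- function(id, sequence, labels8 = NA_character_,
                            labels3 = NA_character_) {
  sequence <- toupper(sequence)
  if (anyDuplicated(id)) {
    stop("duplicate record id: ", id[duplicated(id)][1], call. = FALSE)
  }
  if (any(nchar(sequence) == 0)) stop("empty sequence", call. = FALSE)
  bad <- vapply(strsplit(sequence, "", fixed = TRUE),
                function(ch) any(!ch %in% AA_ALPHABET), logical(1))
  if (any(bad)) {
    stop("sequence for record '", id[bad][1],
         "' contains letters outside the 21-letter alphabet; ",
         "use read_fasta() to normalize first", call. = FALSE)
  }
  recs <- tibble::tibble(id = as.character(id), sequence = sequence,
                         labels8 = labels8, labels3 = labels3)
  recs$labels3 <- ifelse(is.na(recs$labels3) & !is.na(recs$labels8),
                         reduce_to_q3(ifelse(is.na(recs$labels8), "",
                                             recs$labels8)),
                         recs$labels3)
  check_record_labels(recs)
  recs
}

check_record_labels <- function(recs) {
  for (i in seq_len(nrow(recs))) {
    L <- nchar(recs$sequence[i])
    if (!is.na(recs$labels8[i])) {
      validate_labels(recs$labels8[i], q8_alphabet(), recs$id[i])
      if (nchar(recs$labels8[i]) != L) {
        stop(sprintf("record '%s': labels8 length %d != sequence length %d",
                     recs$id[i], nchar(recs$labels8[i]), L), call. = FALSE)
      }
    }
    if (!is.na(recs$labels3[i])) {
      validate_labels(recs$labels3[i], q3_alphabet(), recs$id[i])
      if (nchar(recs$labels3[i]) != L) {
        stop(sprintf("record '%s': labels3 length %d != sequence length %d",
                     recs$id[i], nchar(recs$labels3[i]), L), call. = FALSE)
      }
    }
  }
  invisible(recs)
}

#' Attach labels to records
#'
#' Joins a named set of label strings (as returned by [read_labels()]) onto a
#' record table, validating alphabet membership and lengths.
#'
#' @param records a record tibble from [protein_records()] or [read_fasta()].
#' @param labels named character vector or list, id -> label string.
#' @param alphabet the alphabet the labels are written in.
#' @return the record tibble with `labels8`/`labels3` filled in.
#' @export
attach_labels <- function(records, labels, alphabet = q3_alphabet()) {
  labels <- unlist(labels)
  missing <- setdiff(records$id, names(labels))
  if (length(missing) == length(records$id)) {
    stop("none of the record ids appear in the label set", call. = FALSE)
  }
  col <- if (length(alphabet) == 8) "labels8" else "labels3"
  hit <- records$id %in% names(labels)
  records[[col]][hit] <- unname(labels[records$id[hit]])
  if (col == "labels8") {
    records$labels3[hit] <- reduce_to_q3(records$labels8[hit])
  }
  check_record_labels(records)
  records
}

#' Deterministically split records into training and test sets
#'
#' Whole chains (never residues) are assigned to one side or the other, so no
#' sequence leaks across the split. The partition is a pure function of the
#' record order and the seed.
#'
#' @param records record tibble.
#' @param train_fraction fraction assigned to training (default 0.7, a 7:3
#'   split).
#' @param seed integer seed controlling the permutation.
#' @return a list with tibbles `train` and `test`.
#' @export
split_records <- function(records, train_fraction = 0.7, seed = 1L) {
  n <- nrow(records)
  if (n < 2) stop("need at least 2 records to split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  n_train <- round(train_fraction * n)
  n_train <- max(1L, min(n - 1L, n_train))
  perm <- with_local_seed(seed, sample.int(n))
  idx_train <- sort(perm[seq_len(n_train)])
  list(train = records[idx_train, , drop = FALSE],
       test = records[sort(perm[(n_train + 1L):n]), , drop = FALSE])
}

# Run expr under a private RNG stream; the caller's RNG state is untouched.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
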