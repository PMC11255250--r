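#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and any letter outside the 21-letter alphabet
#' (20 canonical amino acids plus `X`) is mapped to `X`; the number of
#' substitutions is reported with a warning. Wrapped sequence lines and CRLF
#' endings are handled by the underlying Biostrings reader.
#'
#' @param path path to a FASTA file.
#' @return a record tibble (see [protein_records()]); empty file gives an
#'   empty tibble with a warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(tibble::tibble(id = character(), sequence = character(),
                          labels8 = character(), labels3 = character()))
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  n_sub <- 0L
  seqs <- vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- !ch %in% AA_ALPHABET
    if (any(bad)) {
      n_sub <<- n_sub + sum(bad)
      ch[bad] <- "X"
      s <- paste(ch, collapse = "")
    }
    s
  }, character(1), USE.NAMES = FALSE)
  if (n_sub > 0) {
    warning(sprintf("%d non-standard letters mapped to 'X' in '%s'",
                    n_sub, path), call. = FALSE)
  }
  protein_records(ids, seqs)
}

#' Write records to FASTA
#'
#' @param records record tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read per-residue secondary-structure labels
#'
#' Label files are FASTA-like (`.ss3` / `.ss8`): a `>id` header followed by a
#' label string over the given alphabet, possibly wrapped.
#'
#' @param path path to the label file.
#' @param alphabet [q3_alphabet()] or [q8_alphabet()].
#' @return named character vector, id -> label string.
#' @export
read_labels <- function(path, alphabet = q3_alphabet()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate id in label file: ", ids[duplicated(ids)][1],
         call. = FALSE)
  }
  labs <- toupper(as.character(set))
  for (i in seq_along(labs)) validate_labels(labs[i], alphabet, ids[i])
  stats::setNames(labs, ids)
}

#' Write per-residue labels in FASTA-like format
#'
#' @param labels named character vector id -> label string, or a record tibble
#'   (then `column` selects `labels3` or `labels8`).
#' @param path output path.
#' @param column label column to use when `labels` is a record tibble.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, column = "labels3") {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels[[column]], labels$id)
  }
  labels <- labels[!is.na(labels)]
  set <- Biostrings::BStringSet(unname(unlist(labels)))
  names(set) <- names(labels)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
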