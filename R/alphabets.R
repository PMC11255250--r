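#' Secondary-structure state alphabets
#'
#' The 8-state DSSP alphabet is, in fixed order: H (alpha helix), G (3-10
#' helix), I (pi helix), E (extended beta strand), B (isolated beta bridge),
#' T (turn), S (bend), C (coil/other). The reduced 3-state alphabet is
#' H (helix), E (strand), C (coil). Class indices used throughout the package
#' (one-hot columns, probability matrix columns, teacher logit columns) follow
#' these orders.
#'
#' @return A `ss_alphabet` object: a list with `states` (character vector) and
#'   `index_of` (named integer vector of 1-based class indices).
#' @examples
#' q8_alphabet()$states
#' q3_alphabet()$index_of
#' @export
q8_alphabet <- function() {
  new_alphabet(c("H", "G", "I", "E", "B", "T", "S", "C"), "Q8")
}

#' @rdname q8_alphabet
#' @export
q3_alphabet <- function() {
  new_alphabet(c("H", "E", "C"), "Q3")
}

new_alphabet <- function(states, name) {
  stopifnot(!anyDuplicated(states))
  idx <- stats::setNames(seq_along(states), states)
  structure(list(states = states, index_of = idx, name = name),
            class = "ss_alphabet")
}

#' @export
print.ss_alphabet <- function(x, ...) {
  cat("<ss_alphabet ", x$name, ": ", paste(x$states, collapse = ""), ">\n",
      sep = "")
  invisible(x)
}

#' @export
length.ss_alphabet <- function(x) length(x$states)

#' Validate a label string against an alphabet
#'
#' @param labels a single label string.
#' @param alphabet an [q8_alphabet()] or [q3_alphabet()].
#' @param id record identifier used in error messages.
#' @return the input, invisibly, if valid; otherwise an error naming the id
#'   and the first offending position.
#' @export
validate_labels <- function(labels, alphabet, id = "<labels>") {
  chars <- strsplit(labels, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% alphabet$states)
  if (length(bad) > 0) {
    stop(sprintf(
      "record '%s': label character '%s' at position %d is not in the %s alphabet (%s)",
      id, chars[bad[1]], bad[1], alphabet$name,
      paste(alphabet$states, collapse = "")
    ), call. = FALSE)
  }
  invisible(labels)
}

#' Reduce 8-state labels to 3-state labels
#'
#' Positionwise DSSP reduction: H, G, I (helices) map to H; E, B (strands and
#' bridges) map to E; C, S, T (coil, bend, turn) map to C.
#'
#' @param labels8 a character vector of label strings over the Q8 alphabet.
#' @return a character vector of the same lengths over the Q3 alphabet.
#' @examples
#' reduce_to_q3("HGIEBTSC")  # "HHHEECCC"
#' @export
reduce_to_q3 <- function(labels8) {
  vapply(labels8, function(s) {
    if (nchar(s) == 0) return("")
    validate_labels(s, q8_alphabet())
    chartr("HGIEBTSC", "HHHEECCC", s)
  }, character(1), USE.NAMES = FALSE)
}
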