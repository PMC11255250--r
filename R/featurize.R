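#' Per-residue feature matrix for one record
#'
#' Concatenates, per residue, the one-hot block (21 columns), the
#' physicochemical block (7 columns) and the skip-gram embedding block
#' (`emb$dim` columns), giving a constant total width across records.
#'
#' @param sequence residue string.
#' @param emb trained [train_embeddings()] model, or `NULL` to skip the
#'   embedding block.
#' @param table physicochemical matrix from [physchem_table()].
#' @return `L x D` numeric matrix with attribute `record_id` unset.
#' @export
featurize_record <- function(sequence, emb = NULL, table = physchem_table()) {
  oh <- one_hot(sequence)
  pc <- physchem(sequence, table)
  if (is.null(emb)) {
    m <- cbind(oh, pc)
  } else {
    m <- cbind(oh, pc, embed_sequence(emb, sequence))
  }
  stopifnot(all(is.finite(m)))
  unname(m)
}

#' Featurize a table of records
#'
#' @param records record tibble.
#' @param emb embedding model (or `NULL`).
#' @param table physicochemical matrix.
#' @return tibble with columns `id` and a `features` list-column of matrices.
#' @export
featurize_records <- function(records, emb = NULL, table = physchem_table()) {
  tibble::tibble(
    id = records$id,
    features = lapply(records$sequence, featurize_record, emb = emb,
                      table = table)
  )
}

#' Sliding windows over a feature matrix
#'
#' Cuts the per-residue feature matrix into fixed-width windows centered on
#' stride-spaced positions; positions beyond the sequence ends are filled
#' with all-zero padding rows so every window has the same shape.
#'
#' @param features `L x D` matrix.
#' @param width odd window width.
#' @param stride center spacing (>= 1).
#' @return list of `list(center = <1-based index>, window = <width x D>)`.
#' @export
windows <- function(features, width = 19L, stride = 1L) {
  if (width <= 0) stop("width must be positive", call. = FALSE)
  if (width %% 2 == 0) stop("width must be odd", call. = FALSE)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  L <- nrow(features)
  D <- ncol(features)
  half <- (width - 1L) %/% 2L
  centers <- seq.int(1L, L, by = as.integer(stride))
  lapply(centers, function(c0) {
    rows <- (c0 - half):(c0 + half)
    w <- matrix(0, width, D)
    ok <- rows >= 1 & rows <= L
    w[ok, ] <- features[rows[ok], , drop = FALSE]
    list(center = c0, window = w)
  })
}
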