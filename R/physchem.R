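#' One-hot encode a residue string
#'
#' Columns follow the fixed alphabet order A, C, D, E, F, G, H, I, K, L, M, N,
#' P, Q, R, S, T, V, W, Y, X (alphabetical canonical residues, then the
#' unknown symbol).
#'
#' @param sequence residue string over the 21-letter alphabet.
#' @return an `L x 21` 0/1 matrix, one 1 per row.
#' @export
one_hot <- function(sequence) {
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- match(ch, AA_ALPHABET)
  if (anyNA(idx)) {
    stop("invalid residue letter '", ch[which(is.na(idx))[1]], "'",
         call. = FALSE)
  }
  m <- matrix(0, nrow = length(ch), ncol = length(AA_ALPHABET),
              dimnames = list(NULL, AA_ALPHABET))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Physicochemical property table
#'
#' Loads the shipped per-residue property table and expands it to the numeric
#' feature block used by [featurize_record()]: a 4-class polarity one-hot
#' (nonpolar, polar uncharged, positively charged, negatively charged), the
#' net charge at pH 7 (-1/0/+1), molecular weight min-max scaled to \[0, 1\]
#' over the 20 canonical residues, and the Kyte-Doolittle hydropathy index
#' scaled to \[0, 1\]. The unknown residue `X` gets the all-zero vector so it
#' carries no property information.
#'
#' @return a 21 x 7 numeric matrix with rownames over the residue alphabet.
#' @export
physchem_table <- function() {
  path <- system.file("extdata", "physchem_properties.csv", package = "tcnss")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  pol_levels <- c("nonpolar", "polar", "positive", "negative")
  pol <- matrix(0, nrow(tab), 4,
                dimnames = list(NULL, paste0("pol_", pol_levels)))
  pol[cbind(seq_len(nrow(tab)), match(tab$polarity, pol_levels))] <- 1
  scale01 <- function(x) (x - min(x)) / (max(x) - min(x))
  m <- cbind(pol, charge = tab$charge,
             size = scale01(tab$weight),
             hydropathy = scale01(tab$hydropathy))
  rownames(m) <- tab$residue
  out <- rbind(m[AA_ALPHABET[1:20], , drop = FALSE],
               X = rep(0, ncol(m)))
  out
}

#' Physicochemical features for a residue string
#'
#' @param sequence residue string.
#' @param table property matrix from [physchem_table()].
#' @return an `L x 7` numeric matrix.
#' @export
physchem <- function(sequence, table = physchem_table()) {
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- match(ch, rownames(table))
  if (anyNA(idx)) {
    stop("invalid residue letter '", ch[which(is.na(idx))[1]], "'",
         call. = FALSE)
  }
  out <- table[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
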