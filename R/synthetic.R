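#' Configuration for the synthetic sequence generator
#'
#' Labels are drawn from a semi-Markov chain: a state dwells for a geometric
#' number of positions (mean `mean_segment_length[state]`, support >= 1),
#' then jumps to a different state according to the off-diagonal-renormalized
#' transition matrix, so secondary-structure "segments" have controllable
#' lengths. Residues are then emitted per position from the dwelling state's
#' distribution over the 20 canonical amino acids.
#'
#' Default emission rows tilt mass onto a per-state preferred residue set
#' (helix formers for H, beta-branched/aromatic residues for E, breakers for
#' C) with strength `sharpness`: `row = normalize(1 + sharpness * preferred)`.
#'
#' @param n_records number of sequences.
#' @param length_range inclusive (min, max) sequence length.
#' @param alphabet `"Q3"` or `"Q8"`.
#' @param mean_segment_length named/positional vector of per-state mean dwell
#'   lengths (>= 1).
#' @param transition K x K row-stochastic matrix; the diagonal is ignored
#'   (renormalized away) because dwell is explicit. `NULL` = uniform over the
#'   other states.
#' @param emission K x 20 row-stochastic matrix over the canonical residues
#'   (columns in one-hot order); `NULL` = built from `sharpness`.
#' @param sharpness tilt strength of the default emissions; larger separates
#'   the states more.
#' @param seed integer seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_records = 30L, length_range = c(30L, 60L),
                             alphabet = c("Q3", "Q8"),
                             mean_segment_length = NULL,
                             transition = NULL, emission = NULL,
                             sharpness = 4, seed = 1L) {
  alphabet <- match.arg(alphabet)
  ab <- if (alphabet == "Q8") q8_alphabet() else q3_alphabet()
  K <- length(ab)
  if (is.null(mean_segment_length)) {
    mean_segment_length <- if (alphabet == "Q3") {
      c(H = 8, E = 5, C = 6)
    } else {
      c(H = 8, G = 3, I = 3, E = 5, B = 1.5, T = 3, S = 2, C = 5)
    }
  }
  mean_segment_length <- rep_len(mean_segment_length, K)
  if (any(mean_segment_length < 1)) {
    stop("mean segment lengths must be >= 1", call. = FALSE)
  }
  if (is.null(transition)) {
    transition <- matrix(1 / (K - 1), K, K)
    diag(transition) <- 0
  }
  if (!all(dim(transition) == c(K, K)) ||
      any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8)) {
    stop("transition must be a row-stochastic K x K matrix", call. = FALSE)
  }
  if (is.null(emission)) emission <- default_emissions(ab, sharpness)
  if (!all(dim(emission) == c(K, 20)) || any(emission < 0) ||
      any(abs(rowSums(emission) - 1) > 1e-8)) {
    stop("emission must be a row-stochastic K x 20 matrix", call. = FALSE)
  }
  if (length_range[1] < 1 || length_range[2] < length_range[1]) {
    stop("invalid length range", call. = FALSE)
  }
  structure(list(n_records = as.integer(n_records),
                 length_range = as.integer(length_range),
                 alphabet = alphabet,
                 mean_segment_length = mean_segment_length,
                 transition = transition, emission = emission,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Residue propensity sets per state, loosely modeled on helix/strand/coil
# formers; Q8 states inherit the set of their Q3 reduction.
default_emissions <- function(ab, sharpness) {
  canon <- AA_ALPHABET[1:20]
  pref3 <- list(
    H = c("A", "L", "M", "E", "Q", "K", "R"),
    E = c("V", "I", "Y", "F", "W", "T", "C"),
    C = c("G", "P", "N", "S", "D")
  )
  m <- t(vapply(ab$states, function(st) {
    st3 <- if (length(ab) == 8) reduce_to_q3(st) else st
    w <- 1 + sharpness * (canon %in% pref3[[st3]])
    w / sum(w)
  }, numeric(20)))
  dimnames(m) <- list(ab$states, canon)
  m
}

#' Preset generator configurations
#'
#' `"easy"` uses deterministic emissions (one distinct residue per state:
#' H -> A, E -> V, C -> G for Q3), so the label string is a pure function of
#' the residue string and a model can in principle reach 100% accuracy.
#' `"hard"` uses strongly overlapping emissions (`sharpness = 1.5`), so
#' labels are only partly predictable from sequence — the small-data regime
#' where soft teacher targets have headroom to help.
#'
#' @param preset `"default"`, `"easy"` or `"hard"`.
#' @param ... overrides passed on to [generator_config()].
#' @return a `generator_config`.
#' @export
synthetic_preset <- function(preset = c("default", "easy", "hard"), ...) {
  preset <- match.arg(preset)
  args <- list(...)
  if (preset == "easy") {
    ab <- q3_alphabet()
    canon <- AA_ALPHABET[1:20]
    em <- matrix(0, 3, 20, dimnames = list(ab$states, canon))
    em["H", "A"] <- 1; em["E", "V"] <- 1; em["C", "G"] <- 1
    defaults <- list(emission = em, alphabet = "Q3")
  } else if (preset == "hard") {
    defaults <- list(sharpness = 1.5, alphabet = "Q3")
  } else {
    defaults <- list()
  }
  do.call(generator_config, utils::modifyList(defaults, args))
}

#' Generate synthetic labeled protein records
#'
#' @param cfg a [generator_config()].
#' @return a record tibble; for Q8 configurations both `labels8` and the
#'   derived `labels3` are populated.
#' @export
generate_records <- function(cfg) {
  ab <- if (cfg$alphabet == "Q8") q8_alphabet() else q3_alphabet()
  K <- length(ab)
  canon <- AA_ALPHABET[1:20]
  with_local_seed(cfg$seed, {
    ids <- sprintf("syn%03d", seq_len(cfg$n_records))
    seqs <- character(cfg$n_records)
    labs <- character(cfg$n_records)
    # start each chain in the positional stationary law: embedded-chain
    # stationary distribution weighted by mean dwell (geometric dwell is
    # memoryless, so no residual-life correction is needed)
    P0 <- cfg$transition
    diag(P0) <- 0
    P0 <- P0 / rowSums(P0)
    ev <- eigen(t(P0))
    pi_embed <- abs(Re(ev$vectors[, which.min(abs(ev$values - 1))]))
    pi_embed <- pi_embed / sum(pi_embed)
    p_start <- pi_embed * cfg$mean_segment_length
    p_start <- p_start / sum(p_start)
    len_choices <- cfg$length_range[1]:cfg$length_range[2]
    for (r in seq_len(cfg$n_records)) {
      # index into the choice vector: sample(x, 1) on a scalar x would
      # draw from 1:x instead of the single admissible length
      L <- len_choices[sample.int(length(len_choices), 1)]
      states <- integer(0)
      st <- sample.int(K, 1, prob = p_start)
      while (length(states) < L) {
        m <- cfg$mean_segment_length[st]
        dwell <- 1L + stats::rgeom(1, prob = min(1, 1 / m))
        states <- c(states, rep(st, dwell))
        p <- cfg$transition[st, ]
        p[st] <- 0
        if (sum(p) == 0) p <- rep(1, K) * (seq_len(K) != st)
        st <- sample.int(K, 1, prob = p)
      }
      states <- states[1:L]
      labs[r] <- paste(ab$states[states], collapse = "")
      res <- vapply(states, function(s) {
        sample(canon, 1, prob = cfg$emission[s, ])
      }, character(1))
      seqs[r] <- paste(res, collapse = "")
    }
    if (cfg$alphabet == "Q8") {
      protein_records(ids, seqs, labels8 = labs)
    } else {
      protein_records(ids, seqs, labels3 = labs)
    }
  })
}

#' Oracle teacher logits for labeled records
#'
#' A desk-scale stand-in for a large protein language model teacher: each
#' logit row puts `margin` on the true class and 0 elsewhere, plus Gaussian
#' noise with standard deviation `noise_sd`. With zero noise the teacher's
#' argmax reproduces the labels exactly.
#'
#' @param records labeled record tibble.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param margin logit margin of the true class (> 0).
#' @param seed integer seed.
#' @param alphabet alphabet defining class order and the label column used.
#' @return a `teacher_logits` named list id -> `L x K` matrix.
#' @export
oracle_teacher <- function(records, noise_sd = 1, margin = 5, seed = 1L,
                           alphabet = q3_alphabet()) {
  col <- if (length(alphabet) == 8) "labels8" else "labels3"
  K <- length(alphabet)
  with_local_seed(seed, {
    out <- lapply(seq_len(nrow(records)), function(i) {
      lab <- records[[col]][i]
      if (is.na(lab)) stop("record '", records$id[i], "' is unlabeled",
                           call. = FALSE)
      idx <- label_indices(lab, alphabet)
      m <- matrix(0, length(idx), K)
      m[cbind(seq_along(idx), idx)] <- margin
      m + matrix(stats::rnorm(length(m), sd = noise_sd), nrow(m), ncol(m))
    })
    structure(stats::setNames(out, records$id), class = "teacher_logits",
              alphabet = alphabet$name)
  })
}

#' Write a synthetic corpus to disk
#'
#' Emits standard FASTA plus FASTA-like `.ss3`/`.ss8` label files (and, when
#' given, teacher logits as JSON-lines) so a generated corpus is
#' indistinguishable from real inputs to the rest of the pipeline.
#'
#' @param records record tibble.
#' @param dir output directory.
#' @param prefix file name stem.
#' @param teacher optional `teacher_logits`.
#' @return named vector of the written paths, invisibly.
#' @export
write_corpus <- function(records, dir, prefix = "corpus", teacher = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(fasta = file.path(dir, paste0(prefix, ".fasta")))
  write_fasta(records, paths["fasta"])
  if (!all(is.na(records$labels3))) {
    paths["ss3"] <- file.path(dir, paste0(prefix, ".ss3"))
    write_labels(records, paths["ss3"], column = "labels3")
  }
  if (!all(is.na(records$labels8))) {
    paths["ss8"] <- file.path(dir, paste0(prefix, ".ss8"))
    write_labels(records, paths["ss8"], column = "labels8")
  }
  if (!is.null(teacher)) {
    paths["teacher"] <- file.path(dir, paste0(prefix, ".teacher.jsonl"))
    ab <- if (attr(teacher, "alphabet") == "Q8") q8_alphabet() else
      q3_alphabet()
    write_teacher_logits(teacher, paths["teacher"], ab)
  }
  invisible(paths)
}
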