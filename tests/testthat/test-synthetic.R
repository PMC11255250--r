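test_that("generate_records honors the contract and is reproducible", {
  cfg <- generator_config(n_records = 5, length_range = c(30, 60), seed = 7)
  recs <- generate_records(cfg)
  expect_equal(nrow(recs), 5)
  expect_true(all(nchar(recs$sequence) >= 30 & nchar(recs$sequence) <= 60))
  expect_equal(nchar(recs$labels3), nchar(recs$sequence))

  recs2 <- generate_records(cfg)
  expect_identical(recs, recs2)

  # Q8 configurations populate both label columns
  cfg8 <- generator_config(n_records = 3, length_range = c(20, 30),
                           alphabet = "Q8", seed = 3)
  recs8 <- generate_records(cfg8)
  expect_false(anyNA(recs8$labels8))
  expect_equal(recs8$labels3, reduce_to_q3(recs8$labels8))

  expect_error(generator_config(transition = matrix(1, 3, 3)),
               "row-stochastic")
})

test_that("segment dwell follows the configured geometric law", {
  # mean dwell 1 forces all runs to length 1
  cfg1 <- generator_config(n_records = 20, length_range = c(50, 50),
                           mean_segment_length = c(1, 1, 1), seed = 5)
  recs <- generate_records(cfg1)
  runs <- unlist(lapply(recs$labels3, function(x) {
    rle(strsplit(x, "")[[1]])$lengths
  }))
  expect_true(all(runs == 1))

  # larger mean dwell: empirical mean run length within 3 s.e. of the
  # geometric expectation (interior runs only; runs cut by the chain ends
  # are length-biased)
  m <- 4
  cfgm <- generator_config(n_records = 120, length_range = c(90, 90),
                           mean_segment_length = c(m, m, m), seed = 6)
  recs <- generate_records(cfgm)
  runs <- unlist(lapply(recs$labels3, function(x) {
    r <- rle(strsplit(x, "")[[1]])$lengths
    if (length(r) > 2) r[2:(length(r) - 1)] else integer(0)
  }))
  sd_geom <- sqrt((1 - 1 / m)) * m  # sd of 1 + Geom(1/m)
  expect_lt(abs(mean(runs) - m), 3 * sd_geom / sqrt(length(runs)))
})

test_that("deterministic emissions make labels a function of residues", {
  cfg <- synthetic_preset("easy", n_records = 6, length_range = c(30, 50),
                          seed = 9)
  recs <- generate_records(cfg)
  map <- c(A = "H", V = "E", G = "C")
  for (i in seq_len(nrow(recs))) {
    derived <- paste(map[strsplit(recs$sequence[i], "")[[1]]],
                     collapse = "")
    expect_equal(derived, recs$labels3[i])
  }
})

test_that("state frequencies match the semi-Markov stationary law", {
  # positional stationary frequency is proportional to (embedded-chain
  # stationary) x (mean dwell); uniform off-diagonal transitions with K = 3
  # give a uniform embedded chain
  msl <- c(8, 5, 6)
  cfg <- generator_config(n_records = 300, length_range = c(60, 60),
                          mean_segment_length = msl, seed = 13)
  recs <- generate_records(cfg)
  expected_p <- msl / sum(msl)

  # positions inside a run are correlated, so a naive positional chi-square
  # is miscalibrated; each record's FIRST state is an independent draw from
  # the dwell-weighted stationary law and supports a valid chi-square
  first <- substr(recs$labels3, 1, 1)
  obs1 <- table(factor(first, levels = c("H", "E", "C")))
  chisq <- sum((as.numeric(obs1) - nrow(recs) * expected_p)^2 /
               (nrow(recs) * expected_p))
  expect_lt(chisq, stats::qchisq(0.99, df = 2))

  # pooled positional frequencies agree with the same law coarsely
  chars <- unlist(strsplit(recs$labels3, ""))
  freq <- as.numeric(table(factor(chars, levels = c("H", "E", "C")))) /
    length(chars)
  expect_lt(max(abs(freq - expected_p)), 0.03)
})

test_that("oracle_teacher encodes the labels with controllable noise", {
  recs <- generate_records(generator_config(n_records = 4,
                                            length_range = c(20, 30),
                                            seed = 2))
  ab <- q3_alphabet()
  t0 <- oracle_teacher(recs, noise_sd = 0, margin = 5, seed = 1)
  for (i in seq_len(nrow(recs))) {
    am <- max.col(t0[[recs$id[i]]])
    expect_equal(paste(ab$states[am], collapse = ""), recs$labels3[i])
  }
  # noise-free teacher gives zero distillation loss against itself
  expect_equal(kd_loss(t0[[1]], t0[[1]], rho = 2), 0)

  # reproducibility
  t1 <- oracle_teacher(recs, noise_sd = 1, margin = 5, seed = 4)
  t2 <- oracle_teacher(recs, noise_sd = 1, margin = 5, seed = 4)
  expect_identical(t1, t2)
})

test_that("noisy teacher argmax accuracy matches the normal-tail closed form", {
  recs <- generate_records(generator_config(n_records = 150,
                                            length_range = c(70, 70),
                                            seed = 21))
  margin <- 5; sd <- 2
  teach <- oracle_teacher(recs, noise_sd = sd, margin = margin, seed = 8)
  ab <- q3_alphabet()
  hits <- 0; tot <- 0
  for (i in seq_len(nrow(recs))) {
    am <- max.col(teach[[recs$id[i]]])
    obs <- tcnss:::label_indices(recs$labels3[i], ab)
    hits <- hits + sum(am == obs)
    tot <- tot + length(obs)
  }
  # P(margin + sd*Z0 > sd*Zj for all j) = E_z[ Phi(z + margin/sd)^(K-1) ]
  closed <- stats::integrate(function(z) {
    stats::dnorm(z) * stats::pnorm(z + margin / sd)^2
  }, -Inf, Inf)$value
  expect_lt(abs(hits / tot - closed), 0.02)
})

test_that("a generated corpus round-trips through the standard file formats", {
  cfg <- generator_config(n_records = 4, length_range = c(15, 25), seed = 31)
  recs <- generate_records(cfg)
  teach <- oracle_teacher(recs, seed = 1)
  d <- withr::local_tempdir()
  paths <- write_corpus(recs, d, "toy", teacher = teach)
  back <- read_fasta(paths["fasta"])
  expect_equal(back$sequence, recs$sequence)
  labs <- read_labels(paths["ss3"], q3_alphabet())
  expect_equal(unname(labs[recs$id]), recs$labels3)
  tl <- read_teacher_logits(paths["teacher"], q3_alphabet(), records = recs)
  expect_equal(tl[[recs$id[1]]], teach[[recs$id[1]]], tolerance = 1e-12)
})
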