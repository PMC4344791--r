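test_that("profile estimation matches the smoothed count formula", {
  seed <- list(family = "F", rows = c("KKKAC", "KKKAC", "KKK-C"))
  p <- build_profile(seed, pseudocount = 1)
  # column of 3 rows all K with pseudocount 1: (3 + 1) / (3 + 20)
  expect_equal(unname(p$match_emissions[1, "K"]), 4 / 23)
  # column 4 has one gap: n_nongap = 2
  expect_equal(unname(p$match_emissions[4, "A"]), 3 / 22)
  expect_equal(p$L, 5L)

  # all-gap and mostly-gap columns are excluded from match states
  seed2 <- list(family = "G", rows = c("KK-A", "KK-A", "KK-A"))
  expect_equal(build_profile(seed2)$L, 3L)
  expect_error(build_profile(list(family = "H", rows = c("--", "--"))),
               "gap threshold")
})

test_that("emission and transition tables normalise to 1", {
  set.seed(41)
  for (k in 1:5) {
    p <- build_profile(list(family = "R", rows = related_rows()))
    expect_true(all(abs(rowSums(p$match_emissions) - 1) < 1e-9))
    expect_lt(abs(sum(p$background) - 1), 1e-9)
    expect_lt(abs(sum(p$insert_emissions) - 1), 1e-9)
    expect_true(all(abs(rowSums(p$t_m) - 1) < 1e-9))
    expect_true(all(abs(rowSums(p$t_i) - 1) < 1e-9))
    expect_true(all(abs(rowSums(p$t_d) - 1) < 1e-9))
  }
})

test_that("Viterbi on a gapless consensus equals the closed-form diagonal path score", {
  set.seed(42)
  # zero-entropy seed of 8 DISTINCT residues: every diagonal step then has
  # positive emission log-odds net of the M->M transition, so the full
  # diagonal is the optimal local path and the closed form applies
  cons <- paste(sample(AA20, 8, replace = FALSE), collapse = "")
  rows <- rep(cons, 3)
  p <- build_profile(list(family = "Z", rows = rows))
  idx <- match(strsplit(cons, "")[[1]], AA20)
  emis <- sum(log2(p$match_emissions[cbind(1:8, idx)] / p$background[idx]))
  trans <- sum(log2(p$t_m[1:7, "MM"]))  # no indel terms, but M->M is paid
  v <- viterbi_score(p, cons)
  expect_equal(v$bit_score, emis + trans, tolerance = 1e-9)
  expect_equal(c(v$ali_start, v$ali_end), c(0L, 8L))
})

test_that("Viterbi equals exhaustive path enumeration on random toy instances", {
  set.seed(43)
  for (trial in 1:40) {
    p <- random_toy_profile()
    prot <- rand_aa(sample(1:6, 1))
    expect_equal(viterbi_score(p, prot)$bit_score, enum_viterbi(p, prot),
                 tolerance = 1e-9, info = sprintf("L=%d prot=%s", p$L, prot))
  }
})

test_that("a returned hit spans at least one residue and flanking residues are free", {
  set.seed(44)
  p <- build_profile(list(family = "R", rows = related_rows()))
  prot <- rand_aa(30)
  v <- viterbi_score(p, prot)
  expect_lt(v$ali_start, v$ali_end)
  # score shift property: padding outside the aligned span changes nothing
  padded <- paste0(rand_aa(7), prot, rand_aa(9))
  expect_equal(viterbi_score(p, padded)$bit_score, v$bit_score,
               tolerance = 1e-9)
})

test_that("Gumbel calibration yields monotone, clamped, self-consistent E-values", {
  set.seed(45)
  p <- build_profile(list(family = "R", rows = related_rows()))
  p <- calibrate_evalue(p, n_random = 500L, mean_len = 100L, rng_seed = 11L)
  expect_gt(p$gumbel_lambda, 0)
  # closed form at the location parameter: E(mu, N = 1) = 1
  expect_equal(evalue(p, p$gumbel_mu, 1), 1, tolerance = 1e-12)
  # strictly decreasing in the score inside the clamp, clamped to [0, N]
  s <- seq(p$gumbel_mu - 2, p$gumbel_mu + 20, length.out = 50)
  e <- evalue(p, s, 10)
  expect_true(all(diff(e[e < 10 & e > 0]) < 0))
  expect_true(all(e <= 10 & e >= 0))
  expect_error(evalue(build_profile(list(family = "X",
                                         rows = related_rows())), 5, 10),
               "not calibrated")

  # self-consistency: P(score > s at E = 0.01, N = 1) ~ 0.01 on fresh nulls
  s01 <- p$gumbel_mu + log(1 / 0.01) / p$gumbel_lambda
  set.seed(777)
  cnt <- sum(vapply(1:500, function(i)
    viterbi_score(p, rand_aa(100))$bit_score > s01, TRUE))
  expect_true(cnt >= qbinom(0.025, 500, 0.01) &
                cnt <= qbinom(0.975, 500, 0.01))
})

test_that("scanning reports planted domains below threshold and sorts hits", {
  cfg <- synthetic_config(n_tf_transcripts = 9L, n_background = 0L,
                          duplicate_rate = 0, n_blast_update = 0L,
                          n_filtered_recovery = 0L, rng_seed = 46L)
  corp <- generate_corpus(cfg)
  prots <- translate_corpus(corp$ests)
  profs <- lapply(corp$seeds, build_profile)
  profs <- lapply(seq_along(profs), function(i)
    calibrate_evalue(profs[[i]], 200L, 100L, rng_seed = 46L + i))
  hits <- scan_proteins(prots, profs, e_max = 0.01)
  tru <- corp$truth
  for (i in seq_len(nrow(prots))) {
    fam <- tru$true_family[tru$est_id == prots$source_id[i]]
    h <- hits[hits$protein_id == prots$protein_id[i], ]
    expect_true(fam %in% h$family, info = prots$source_id[i])
  }
  expect_true(all(hits$e_value < 0.01))
  expect_false(is.unsorted(hits$protein_id))
  # empty scans
  expect_equal(nrow(scan_proteins(prots[0, ], profs)), 0L)
  expect_error(scan_proteins(prots, lapply(corp$seeds, build_profile)),
               "uncalibrated")
})

test_that("profiles survive a JSON round trip", {
  set.seed(47)
  p <- calibrate_evalue(build_profile(list(family = "R",
                                           rows = related_rows())),
                        200L, 80L, rng_seed = 5L)
  path <- withr::local_tempfile(fileext = ".json")
  write_profile_json(p, path)
  q <- read_profile_json(path)
  expect_equal(q$match_emissions, p$match_emissions, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(q$gumbel_mu, p$gumbel_mu)
  expect_equal(q$gumbel_lambda, p$gumbel_lambda)
  prot <- rand_aa(40)
  expect_equal(viterbi_score(q, prot)$bit_score,
               viterbi_score(p, prot)$bit_score, tolerance = 1e-9)
})

test_that("seed alignments load from aligned FASTA and Stockholm", {
  dir <- withr::local_tempdir()
  seed <- list(family = "FAMX", rows = c("ACD-K", "ACDEK", "ACD-K"))
  fa <- file.path(dir, "FAMX.afa")
  write_seed_alignment(seed, fa)
  back <- read_seed_alignment(fa, family = "FAMX")
  expect_equal(back$rows, seed$rows)
  sto <- file.path(dir, "FAMX.sto")
  writeLines(c("# STOCKHOLM 1.0", "row1 ACD-K", "row2 ACDEK", "row3 ACD-K",
               "//"), sto)
  back2 <- read_seed_alignment(sto, family = "FAMX")
  expect_equal(toupper(gsub("\\.", "-", back2$rows)), seed$rows)
})
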