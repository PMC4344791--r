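test_that("family seeds are conserved within and divergent between families", {
  cfg <- synthetic_config(n_families = 2L, core_len = 30L, rng_seed = 71L)
  fam <- generate_family_seeds(cfg)
  expect_length(fam$seeds, 2L)
  # consensus divergence: cores differ at >= 60% of positions (18/30)
  c1 <- strsplit(fam$seeds[[1]]$consensus, "")[[1]]
  c2 <- strsplit(fam$seeds[[2]]$consensus, "")[[1]]
  expect_gte(sum(c1 != c2), 18L)
  # within-family conservation: >= 60% identical columns in each alignment
  for (s in fam$seeds) {
    m <- do.call(rbind, strsplit(s$rows, ""))
    ident_cols <- mean(apply(m, 2, function(col) length(unique(col)) == 1))
    expect_gte(ident_cols, 0.6)
  }
  # rules: own family required, all others forbidden
  expect_equal(fam$rules[[1]]$required, list("FAM01"))
  expect_equal(fam$rules[[1]]$forbidden, "FAM02")
  expect_error(generate_family_seeds(synthetic_config(n_families = 0L)),
               "n_families")
  # impossible worlds error: tiny cores cannot satisfy the divergence and
  # detectability constraints for many families
  expect_error(
    generate_family_seeds(synthetic_config(n_families = 400L,
                                           core_len = 10L, rng_seed = 1L)),
    "unsatisfiable|could not construct")
})

test_that("corpus generation is deterministic and the truth table covers every EST once", {
  cfg <- synthetic_config(n_tf_transcripts = 8L, n_background = 5L,
                          rng_seed = 72L)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a, b)
  # byte-identical files
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic(a, d1); write_synthetic(b, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  # a different seed gives a different corpus
  expect_false(identical(
    generate_corpus(synthetic_config(n_tf_transcripts = 8L, n_background = 5L,
                                     rng_seed = 73L))$ests, a$ests))
  # coverage: one truth row per EST
  expect_setequal(a$truth$est_id, a$ests$id)
  expect_equal(anyDuplicated(a$truth$est_id), 0L)
  # every duplicate refers to an existing EST
  dups <- a$truth$is_duplicate_of[!is.na(a$truth$is_duplicate_of)]
  expect_true(all(dups %in% a$ests$id))
  # background rows have no family
  expect_true(all(is.na(a$truth$true_family[grepl("^BG", a$truth$est_id)])))
})

test_that("duplicate planting matches the configured rate and stays above 0.95 identity", {
  cfg <- synthetic_config(n_tf_transcripts = 20L, n_background = 0L,
                          duplicate_rate = 0.5, n_blast_update = 0L,
                          n_filtered_recovery = 0L, rng_seed = 74L)
  corp <- generate_corpus(cfg)
  dups <- corp$truth[!is.na(corp$truth$is_duplicate_of), ]
  # binomial(20, 0.5) planting; the exact count is read from the truth table
  expect_gt(nrow(dups), 0L)
  expect_lt(nrow(dups), 20L)
  for (i in seq_len(nrow(dups))) {
    s1 <- corp$ests$sequence[corp$ests$id == dups$est_id[i]]
    s2 <- corp$ests$sequence[corp$ests$id == dups$is_duplicate_of[i]]
    expect_gte(pairwise_identity(s1, s2, "nucleotide"), 0.95)
    expect_lt(nchar(s1), nchar(s2))   # duplicates are shorter than originals
  }
  # clustering at 0.95 removes exactly the planted duplicates
  cl <- greedy_cluster(setNames(corp$ests$sequence, corp$ests$id), 0.95,
                       alphabet = "nucleotide")
  expect_equal(sort(names(cluster_map(cl))), sort(dups$est_id))
})

test_that("an all-background corpus yields no planted TFs, only chance-level false positives", {
  cfg <- synthetic_config(n_tf_transcripts = 0L, n_background = 5L,
                          n_blast_update = 0L, n_filtered_recovery = 0L,
                          rng_seed = 75L)
  corp <- generate_corpus(cfg)
  res <- suppressMessages(
    run_pipeline(corp$ests, corp$libraries, corp$seeds, corp$rules,
                 pipeline_config(rng_seed = 75L)))
  # with no planted domains every record (if any) is a scanner false
  # positive from a background EST, within the binomial tolerance the
  # E-value threshold implies (expected false hits ~ e_max per family)
  expect_true(all(grepl("^BG", res$tf_records$source_est_id)))
  expect_lte(nrow(res$tf_records), 2L)
})

test_that("scenario counts are validated against the specific-TF pool", {
  expect_error(generate_corpus(
    synthetic_config(n_tf_transcripts = 2L, n_blast_update = 2L,
                     n_filtered_recovery = 2L, rng_seed = 76L)),
    "scenario counts")
  expect_error(synthetic_config(duplicate_identity = 0.90), "0.95")
  expect_error(synthetic_config(planted_specific_fraction = 1.5), "\\[0, 1\\]")
})
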