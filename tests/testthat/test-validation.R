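test_that("local alignment matches the DP oracle and reports exact identities", {
  a <- strrep("ACGTGGCCAT", 3)
  h <- local_align(a, a)
  expect_equal(h$identity, 1.0)
  expect_equal(h$aln_length, 30L)

  v <- strsplit(a, "")[[1]]
  v[c(5, 14, 23)] <- c("T", "A", "C")   # 3 substitutions
  b <- paste(v, collapse = "")
  h2 <- local_align(a, b)
  expect_equal(h2$aln_length, 30L)
  expect_equal(h2$identity, 27 / 30)

  set.seed(61)
  for (k in 1:50) {
    x <- rand_nt(sample(15:40, 1)); y <- rand_nt(sample(15:40, 1))
    expect_equal(local_align(x, y)$score, gotoh_local_score(x, y),
                 info = paste(x, y))
  }
  # unrelated sequences: a short chance alignment is still returned
  set.seed(62)
  h3 <- local_align(rand_nt(30), rand_nt(30))
  expect_lt(h3$aln_length, 30L)
  expect_gte(h3$aln_length, 1L)
  expect_error(local_align("", "ACGT"), "empty")
})

test_that("matched-sequence criteria use the quoted strict/inclusive boundaries", {
  mk <- function(ratio, ident, qlen, slen) data.frame(
    aln_length = round(ratio * qlen), query_length = qlen,
    subject_length = slen, identity = ident)
  expect_true(is_matched(mk(0.96, 0.85, 100, 120)))
  expect_false(is_matched(mk(0.95, 0.99, 100, 120)))  # "greater than 0.95" strict
  expect_false(is_matched(mk(0.99, 0.80, 100, 100)))  # subject must be longer
  expect_true(is_matched(mk(0.99, 0.80, 100, 101)))   # identity 0.80 inclusive
  expect_false(is_matched(mk(0.99, 0.79, 100, 120)))
  expect_error(is_matched(mk(0.99, 1.2, 100, 120)), "identity")
})

mk_tf_world <- function() {
  tfs <- data.frame(tf_id = c("TaTF00001", "TaTF00002"),
                    source_est_id = c("e1", "e2"), stringsAsFactors = FALSE)
  pres <- matrix(c(0L, 0L, 0L, 0L, 1L, 0L, 0L,
                   0L, 0L, 1L, 0L, 0L, 0L, 0L), 2, 7, byrow = TRUE,
                 dimnames = list(tfs$tf_id, presence_order("stage")))
  l2c <- c(LV = "vegetative", LS = "seedling", LR = "reproductive")
  list(tfs = tfs, pres = pres, l2c = l2c)
}

test_that("matched hits add categories monotonically and idempotently", {
  w <- mk_tf_world()
  hit <- data.frame(query_id = "e1", subject_id = "s1", identity = 0.9,
                    aln_length = 98, query_length = 100, subject_length = 150,
                    subject_library_id = "LV", stringsAsFactors = FALSE)
  up <- update_from_matches(w$tfs, w$pres, hit, w$l2c, "stage")
  expect_equal(up$presence["TaTF00001", "vegetative"], 1L)
  expect_equal(nrow(up$changes), 1L)
  expect_equal(up$changes$source, "blast_update")
  # the TF flips from specific to unspecific
  expect_equal(classify_specific(up$presence)$flag[1], "unspecific")
  # idempotence: reapplying adds nothing
  up2 <- update_from_matches(w$tfs, up$presence, hit, w$l2c, "stage")
  expect_equal(up2$presence, up$presence)
  expect_equal(nrow(up2$changes), 0L)
  # same-category subject: no change, no log entry
  hit_same <- transform(hit, subject_library_id = "LS")
  up3 <- update_from_matches(w$tfs, w$pres, hit_same, w$l2c, "stage")
  expect_equal(up3$presence, w$pres)
  expect_equal(nrow(up3$changes), 0L)
  # unmatched hit (coverage at the boundary) is ignored
  hit_un <- transform(hit, aln_length = 95)
  up4 <- update_from_matches(w$tfs, w$pres, hit_un, w$l2c, "stage")
  expect_equal(up4$presence, w$pres)
  expect_error(update_from_matches(w$tfs, w$pres,
                                   transform(hit, query_id = "eX"),
                                   w$l2c, "stage"), "unknown query")
  # monotonicity: bits never decrease, so specific counts never increase
  expect_true(all(up$presence >= w$pres))
})

test_that("the change log replays to the final matrices", {
  w <- mk_tf_world()
  hits <- data.frame(query_id = c("e1", "e2"), subject_id = c("s1", "s2"),
                     identity = c(0.9, 0.88),
                     aln_length = c(98, 99), query_length = c(100, 100),
                     subject_length = c(150, 140),
                     subject_library_id = c("LV", "LR"),
                     stringsAsFactors = FALSE)
  up <- update_from_matches(w$tfs, w$pres, hits, w$l2c, "stage")
  expect_equal(replay_changes(w$pres, up$changes), up$presence)
})

test_that("filtered-out TF duplicates donate their library categories", {
  cfg <- synthetic_config(n_tf_transcripts = 4L, n_background = 2L,
                          duplicate_rate = 0, n_blast_update = 0L,
                          n_filtered_recovery = 1L, rng_seed = 63L)
  corp <- generate_corpus(cfg)
  res <- run_pipeline(corp$ests, corp$libraries, corp$seeds, corp$rules,
                      pipeline_config(rng_seed = 63L))
  rec <- res$changes[res$changes$source == "filtered_recovery", ]
  expect_gte(nrow(rec), 1L)
  # the recovered TF is now unspecific on the axes that gained a category
  tr <- corp$truth
  fr_est <- tr$est_id[tr$planted_scenario == "filtered_recovery" &
                        is.na(tr$is_duplicate_of)]
  tf <- res$tf_records$tf_id[res$tf_records$source_est_id == fr_est]
  expect_equal(res$stage_flags$flag[res$stage_flags$tf_id == tf], "unspecific")
  expect_equal(res$tissue_flags$flag[res$tissue_flags$tf_id == tf], "unspecific")
  # same-category recovery adds nothing (duplicate-free plain TFs unchanged)
  plain_ests <- tr$est_id[tr$planted_scenario == "plain" &
                            is.na(tr$is_duplicate_of)]
  plain_tfs <- res$tf_records$tf_id[res$tf_records$source_est_id %in% plain_ests]
  expect_true(all(res$stage_flags$flag[res$stage_flags$tf_id %in% plain_tfs] ==
                    "specific"))
})

test_that("external hit tables load with fraction-normalised identities", {
  dir <- withr::local_tempdir()
  hits <- file.path(dir, "hits.tsv")
  writeLines("q1\ts1\t92.5\t98\t5\t1\t1\t98\t1\t98\t1e-30\t150", hits)
  side <- file.path(dir, "side.tsv")
  writeLines(c("subject_id\tlibrary_id", "s1\tLV"), side)
  h <- read_hit_table(hits, side, c(q1 = 100), c(s1 = 150))
  expect_equal(h$identity, 0.925)
  expect_equal(h$subject_library_id, "LV")
  expect_equal(h$query_length, 100)
  expect_true(is_matched(h))
})
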