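test_that("pairwise identity follows the shorter-sequence cd-hit convention", {
  s <- strrep("ACGT", 5)
  expect_equal(pairwise_identity(s, s), 1.0)
  mut <- paste0(substr(s, 1, 10), "T", substr(s, 12, 20))  # one substitution
  expect_equal(pairwise_identity(s, mut), 0.95)
  expect_equal(pairwise_identity(mut, s), 0.95)            # symmetric
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0.0)
  # denominator is the shorter sequence: a perfect 10-mer inside a 20-mer
  expect_equal(pairwise_identity("ACGTACGTAC", s), 1.0)
  expect_error(pairwise_identity("", "ACGT"), "empty")
  # ambiguity characters never count as identical
  expect_equal(pairwise_identity("AAANAAA", "AAANAAA"), 6 / 7)
})

test_that("greedy clustering handles the documented toy cases", {
  s <- strrep("ACGT", 5)
  r <- setNames(c(s, s, s), c("a", "b", "c"))
  cl <- greedy_cluster(r, 0.95, alphabet = "nucleotide")
  expect_length(cl, 1L)
  expect_length(cl[[1]]$member_ids, 2L)

  mut <- paste0(substr(s, 1, 10), "T", substr(s, 12, 20))
  cl2 <- greedy_cluster(setNames(c(s, mut), c("a", "b")), 1.0,
                        alphabet = "nucleotide")
  expect_length(cl2, 2L)  # 0.95 < 1.0: two singletons

  # planted pairs at ~0.96 identity cluster together at 0.95
  set.seed(31)
  base <- replicate(3, rand_nt(50))
  mut1 <- vapply(base, function(x) {
    i <- sample(10:40, 2)
    v <- strsplit(x, "")[[1]]
    v[i] <- vapply(v[i], function(ch) sample(setdiff(NT4, ch), 1), "")
    paste(v, collapse = "")
  }, "")
  r3 <- setNames(c(base, mut1), paste0("s", 1:6))
  cl3 <- greedy_cluster(r3, 0.95, alphabet = "nucleotide")
  expect_length(cl3, 3L)
  expect_equal(cluster_signature(cl3),
               cluster_signature(replay_cluster(r3, 0.95, "nucleotide")))
})

test_that("clustering partitions the input and the representative is the longest member", {
  set.seed(32)
  for (rep in 1:5) {
    n <- sample(8:15, 1)
    base <- rand_nt(60)
    recs <- setNames(vapply(seq_len(n), function(i) {
      v <- strsplit(base, "")[[1]]
      k <- sample(0:8, 1)
      if (k > 0) { i2 <- sample(60, k); v[i2] <- sample(NT4, k, TRUE) }
      paste(v[1:sample(40:60, 1)], collapse = "")
    }, ""), paste0("q", seq_len(n)))
    cl <- greedy_cluster(recs, 0.9, alphabet = "nucleotide")
    ids <- unlist(lapply(cl, function(x) c(x$representative_id, x$member_ids)))
    expect_setequal(ids, names(recs))
    expect_equal(anyDuplicated(ids), 0L)
    for (x in cl) {
      lens <- nchar(recs[c(x$representative_id, x$member_ids)])
      expect_true(all(lens[1] >= lens))
      for (m in x$member_ids)
        expect_gte(pairwise_identity(recs[x$representative_id], recs[m],
                                     "nucleotide"), 0.9)
    }
  }
})

test_that("redundant_count counts non-representative members", {
  mk <- function(sizes) lapply(seq_along(sizes), function(i)
    list(representative_id = paste0("r", i),
         member_ids = if (sizes[i] > 1) paste0("m", i, 1:(sizes[i] - 1))
                      else character(),
         threshold = 1))
  expect_equal(redundant_count(mk(rep(1, 5))), 0L)
  expect_equal(redundant_count(mk(4)), 3L)
  expect_equal(redundant_count(mk(c(3, 2, 1, 1))), 3L)  # 7 sequences - 4 clusters
})

test_that("cross-set redundancy reports mixed-cluster sequences and is threshold-monotone", {
  set.seed(33)
  a <- setNames(replicate(4, rand_nt(40)), paste0("a", 1:4))
  b <- setNames(replicate(4, rand_nt(40)), paste0("b", 1:4))
  rep1 <- cross_set_redundancy(list(A = a, B = b), thresholds = c(0.85, 1.0))
  expect_true(all(rep1$redundant_count[rep1$combination == "A+B"] == 0))

  # one shared sequence at threshold 1.0 -> cross count 2
  b2 <- b; b2[["b1"]] <- a[["a1"]]
  rep2 <- cross_set_redundancy(list(A = a, B = b2), thresholds = 1.0,
                               combinations = list(c("A", "B")))
  expect_equal(rep2$redundant_count, 2L)

  # monotonicity: counts non-increasing as the threshold rises
  set.seed(34)
  fam <- rand_nt(60)
  pool <- setNames(vapply(1:12, function(i) {
    v <- strsplit(fam, "")[[1]]
    k <- sample(0:12, 1)
    if (k > 0) { idx <- sample(60, k); v[idx] <- sample(NT4, k, TRUE) }
    paste(v, collapse = "")
  }, ""), paste0("p", 1:12))
  rep3 <- cross_set_redundancy(list(P = pool),
                               thresholds = c(0.85, 0.9, 0.95, 1.0))
  cnt <- rep3$redundant_count[order(rep3$threshold)]
  expect_true(all(diff(cnt) <= 0))

  expect_error(cross_set_redundancy(list(A = a), combinations = list("Z")),
               "unknown set")
})

test_that("the k-mer prefilter never changes the clustering at threshold 0.95", {
  set.seed(35)
  base <- rand_nt(80)
  recs <- setNames(vapply(1:10, function(i) {
    v <- strsplit(base, "")[[1]]
    k <- sample(c(0, 2, 30), 1)
    if (k > 0) { idx <- sample(80, k); v[idx] <- sample(NT4, k, TRUE) }
    paste(v, collapse = "")
  }, ""), paste0("k", 1:10))
  with_pf <- greedy_cluster(recs, 0.95, alphabet = "nucleotide",
                            use_prefilter = TRUE)
  without <- greedy_cluster(recs, 0.95, alphabet = "nucleotide",
                            use_prefilter = FALSE)
  expect_equal(cluster_signature(with_pf), cluster_signature(without))
})
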