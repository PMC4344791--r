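mk_presence <- function(rows, axis = "stage") {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(sprintf("TaTF%05d", seq_len(nrow(m))),
                      presence_order(axis))
  storage.mode(m) <- "integer"
  m
}

test_that("presence cells are the union of cluster member library categories", {
  tfs <- data.frame(tf_id = c("TaTF00001", "TaTF00002"),
                    source_est_id = c("e1", "e3"), stringsAsFactors = FALSE)
  clusters <- list(list(representative_id = "e1", member_ids = c("e2")),
                   list(representative_id = "e3", member_ids = character()))
  e2l <- c(e1 = "L1", e2 = "L2", e3 = "L3")
  l2c <- c(L1 = "root", L2 = "root", L3 = "leaf")
  m <- build_presence(tfs, clusters, e2l, l2c, "tissue")
  expect_equal(unname(m["TaTF00001", ]), c(0L, 0L, 0L, 1L, 0L, 0L, 0L))
  # two categories when member libraries differ
  l2c2 <- c(L1 = "leaf", L2 = "root", L3 = "seed")
  m2 <- build_presence(tfs, clusters, e2l, l2c2, "tissue")
  expect_equal(unname(m2["TaTF00001", c("leaf", "root")]), c(1L, 1L))
  expect_error(build_presence(tfs, clusters, c(e1 = "L1"), l2c, "tissue"),
               "without library")
})

test_that("specific/unspecific/unclear classification partitions the TF set", {
  m <- mk_presence(list(c(1, 0, 0, 0, 0, 0, 0),    # specific(dormant_seed)
                        c(0, 0, 0, 0, 0, 0, 1),    # unclear
                        c(0, 0, 1, 0, 1, 0, 0),    # unspecific
                        c(0, 0, 0, 1, 0, 0, 1)))   # catch-all ignored
  fl <- classify_specific(m)
  expect_equal(fl$flag, c("specific", "unclear", "unspecific", "specific"))
  expect_equal(fl$specific_category[1], "dormant_seed")
  expect_equal(fl$specific_category[4], "ripening")
  expect_true(all(table(fl$flag) >= 0))
  expect_error(classify_specific(mk_presence(list(rep(0, 7)))), "all-zero")

  # partition property on random matrices
  set.seed(51)
  for (k in 1:10) {
    r <- matrix(rbinom(70, 1, 0.4), 10, 7)
    r[rowSums(r) == 0, 7] <- 1L
    rownames(r) <- sprintf("T%02d", 1:10)
    colnames(r) <- presence_order("tissue")
    f <- classify_specific(r)
    expect_equal(nrow(f), 10L)
    expect_true(all(f$flag %in% c("specific", "unspecific", "unclear")))
    n_inf <- rowSums(r[, 1:6])
    expect_equal(f$flag == "specific", unname(n_inf == 1))
    expect_equal(f$flag == "unclear", unname(n_inf == 0))
  }
})

test_that("family tables satisfy the sum and percentage arithmetic", {
  tfs <- data.frame(tf_id = sprintf("T%02d", 1:5),
                    family = c("F", "F", "F", "G", "G"),
                    stringsAsFactors = FALSE)
  flags <- data.frame(tf_id = tfs$tf_id,
                      flag = c("specific", "specific", "unspecific",
                               "specific", "unclear"),
                      specific_category = c("root", "root", NA, "leaf", NA),
                      stringsAsFactors = FALSE)
  tab <- family_category_table(tfs, flags, families = c("F", "G"),
                               axis = "tissue")
  expect_equal(tab$table["F", "root"], 2L)
  expect_equal(tab$table["F", "sum_specific"], 2L)
  expect_equal(tab$table["G", "other"], 1L)
  expect_equal(unname(tab$totals["sum_specific"]),
               sum(tab$table$sum_specific))
  # row sums over informative columns equal sum_specific
  inf <- presence_order("tissue")[1:6]
  expect_equal(rowSums(tab$table[, inf]), tab$table$sum_specific,
               ignore_attr = TRUE)
  # percentage footer: 342 specific of 2407 -> 14.21
  expect_equal(fraction_report(342, 2407), 14.21)
})

test_that("Venn region counts partition the rows and match a brute-force tally", {
  m1 <- mk_presence(list(c(1, 0, 0, 0, 0, 0, 0), c(0, 1, 0, 0, 0, 0, 0),
                         c(0, 0, 0, 0, 0, 1, 0)))
  v1 <- venn_region_counts(m1)
  expect_length(v1$regions, 127L)
  expect_equal(sum(v1$regions), 3L)
  expect_equal(sum(v1$regions > 0), 3L)

  all_on <- mk_presence(list(rep(1, 7)))
  v2 <- venn_region_counts(all_on)
  expect_equal(unname(v2$regions["1111111"]), 1L)
  expect_true(all(v2$category_totals == 1))

  set.seed(52)
  r <- matrix(rbinom(350, 1, 0.5), 50, 7)
  r[rowSums(r) == 0, 1] <- 1L
  rownames(r) <- sprintf("T%02d", 1:50)
  colnames(r) <- presence_order("stage")
  v3 <- venn_region_counts(r)
  expect_equal(sum(v3$regions), 50L)
  # independent tally: count each observed pattern directly
  pats <- apply(r, 1, paste, collapse = "")
  for (p in unique(pats))
    expect_equal(unname(v3$regions[p]), sum(pats == p))
  # per-category totals are sums over patterns containing the category
  for (k in 1:7) {
    with_k <- sum(v3$regions[substr(names(v3$regions), k, k) == "1"])
    expect_equal(with_k, unname(v3$category_totals[k]))
  }
  # specific counts never exceed category totals
  fl <- classify_specific(r)
  for (cc in presence_order("stage")[1:6])
    expect_lte(sum(fl$specific_category == cc, na.rm = TRUE),
               v3$category_totals[cc])
})
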