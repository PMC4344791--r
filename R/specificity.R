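# Stage/tissue presence matrices, specific/unspecific/unclear calls,
# family-by-category tables and 7-set Venn region counts.

#' Build a presence matrix from cluster membership and library categories
#'
#' A TF is present in category `c` iff any EST of its cluster
#' (representative plus members) comes from a library of category `c`.
#' Columns follow [presence_order()] (six informative categories, catch-all
#' last).
#'
#' @param tf_records TF-record data.frame (needs `tf_id`, `source_est_id`).
#' @param clusters Clusters over EST ids ([greedy_cluster()] output, or any
#'   list of `representative_id`/`member_ids`); each TF's source EST must
#'   appear in exactly one cluster. A TF whose EST appears in no cluster is
#'   treated as a singleton cluster.
#' @param est_to_library Named character vector `est_id -> library_id`.
#' @param library_categories Named character vector
#'   `library_id -> category` for the chosen axis (see
#'   [categorize_libraries()]).
#' @param axis `"stage"` or `"tissue"`.
#' @return Integer 0/1 matrix, rows = `tf_id`, 7 category columns.
#' @export
build_presence <- function(tf_records, clusters, est_to_library,
                           library_categories, axis = c("stage", "tissue")) {
  axis <- match.arg(axis)
  cats <- presence_order(axis)
  est_cluster <- lapply(clusters, function(cl) c(cl$representative_id, cl$member_ids))
  owner <- rep(seq_along(est_cluster), lengths(est_cluster))
  names(owner) <- unlist(est_cluster)
  m <- matrix(0L, nrow(tf_records), 7L,
              dimnames = list(tf_records$tf_id, cats))
  for (i in seq_len(nrow(tf_records))) {
    est <- tf_records$source_est_id[i]
    ests <- if (!is.na(owner[est])) est_cluster[[owner[est]]] else est
    libs <- est_to_library[ests]
    if (any(is.na(libs))) stop("EST without library annotation: ",
                               paste(ests[is.na(libs)], collapse = ", "))
    cc <- library_categories[libs]
    if (any(is.na(cc))) stop("library without category: ",
                             paste(unique(libs[is.na(cc)]), collapse = ", "))
    m[i, unique(cc)] <- 1L
  }
  m
}

#' Classify TFs as specific, unspecific or unclear
#'
#' A TF is specific to category `c` iff exactly one of the six informative
#' columns is set — the catch-all column is ignored for this test; unclear
#' iff all six informative columns are zero and the catch-all is set;
#' unspecific otherwise (two or more informative categories). The three
#' classes partition the TF set.
#'
#' @param matrix Presence matrix from [build_presence()].
#' @return data.frame `tf_id`, `flag` (`"specific"`, `"unspecific"`,
#'   `"unclear"`), `specific_category` (NA unless specific).
#' @export
classify_specific <- function(matrix) {
  if (nrow(matrix) == 0L)
    return(data.frame(tf_id = character(), flag = character(),
                      specific_category = character(),
                      stringsAsFactors = FALSE))
  if (any(rowSums(matrix) == 0L)) stop("all-zero presence row")
  inf <- matrix[, 1:6, drop = FALSE]
  n_inf <- rowSums(inf)
  flag <- ifelse(n_inf == 1L, "specific",
                 ifelse(n_inf == 0L, "unclear", "unspecific"))
  spec_cat <- rep(NA_character_, nrow(matrix))
  one <- which(n_inf == 1L)
  spec_cat[one] <- colnames(inf)[max.col(inf[one, , drop = FALSE])]
  data.frame(tf_id = rownames(matrix), flag = flag,
             specific_category = spec_cat, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Family-by-category table of specific TFs
#'
#' One row per family: counts of TFs specific to each of the six
#' informative categories, their row sum (`sum_specific`), and the number
#' of unclear (catch-all) TFs. A footer gives per-category totals and
#' percentages of the full catalog (half-up, 2 decimals).
#'
#' @param tf_records TF-record data.frame (`tf_id`, `family`).
#' @param flags Output of [classify_specific()].
#' @param families Families to tabulate (rows, in order); default = families
#'   present in `tf_records`.
#' @param n_total Denominator for the percentage footer; defaults to
#'   `nrow(tf_records)`.
#' @param axis `"stage"` or `"tissue"` (sets the column names).
#' @return List with `table` (family rows), `totals` (per-category specific
#'   counts plus `sum_specific` and catch-all), `percentages` (same layout,
#'   2-decimal percentages of `n_total`).
#' @export
family_category_table <- function(tf_records, flags, families = NULL,
                                  n_total = NULL,
                                  axis = c("stage", "tissue")) {
  axis <- match.arg(axis)
  cats <- presence_order(axis)
  inf <- cats[1:6]
  if (is.null(families)) families <- sort(unique(tf_records$family))
  if (is.null(n_total)) n_total <- nrow(tf_records)
  fam_of <- stats::setNames(tf_records$family, tf_records$tf_id)
  tab <- matrix(0L, length(families), 8L,
                dimnames = list(families, c(inf, "sum_specific", cats[7])))
  sp <- flags[flags$flag == "specific", , drop = FALSE]
  for (i in seq_len(nrow(sp))) {
    f <- fam_of[sp$tf_id[i]]
    tab[f, sp$specific_category[i]] <- tab[f, sp$specific_category[i]] + 1L
  }
  un <- flags[flags$flag == "unclear", , drop = FALSE]
  for (i in seq_len(nrow(un))) {
    f <- fam_of[un$tf_id[i]]
    tab[f, cats[7]] <- tab[f, cats[7]] + 1L
  }
  tab[, "sum_specific"] <- rowSums(tab[, inf, drop = FALSE])
  totals <- colSums(tab)
  percentages <- if (n_total >= 1)
    vapply(totals, function(x) fraction_report(x, n_total), 0)
  else totals * 0
  list(table = as.data.frame(tab), totals = totals, percentages = percentages)
}

#' Venn region counts of a 7-category presence matrix
#'
#' Tallies each of the 127 non-empty membership patterns (the regions of a
#' 7-set Venn diagram) and the per-category totals. Region counts partition
#' the TF set; a category's total is the sum over all patterns containing
#' it.
#'
#' @param matrix Presence matrix from [build_presence()].
#' @return List with `regions` (named integer vector over all 127 patterns,
#'   names = 7-bit strings in column order) and `category_totals`.
#' @export
venn_region_counts <- function(matrix) {
  if (ncol(matrix) != 7L) stop("presence matrix must have 7 columns")
  if (nrow(matrix) > 0L && any(rowSums(matrix) == 0L))
    stop("all-zero presence row")
  pats <- apply(matrix, 1L, paste, collapse = "")
  all_pats <- vapply(1:127, function(k) {
    paste(rev(as.integer(intToBits(k)[1:7])), collapse = "")
  }, "")
  counts <- stats::setNames(integer(127), all_pats)
  tt <- table(pats)
  counts[names(tt)] <- as.integer(tt)
  list(regions = counts,
       category_totals = colSums(matrix))
}
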