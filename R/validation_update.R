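# Matched-alignment validation of putative specific TFs and recovery of
# library annotations from filtered-out (clustered-away) sequences. Both
# operations only ever set presence bits, so the specific-TF count is
# non-increasing through validation.

#' Matched-sequence test for an alignment hit
#'
#' A hit is a matched sequence iff (i) alignment length / query length is
#' strictly greater than 0.95, (ii) identity is at least 0.80, and (iii) the
#' subject is strictly longer than the query.
#'
#' @param hit One-row data.frame (or list) with `aln_length`,
#'   `query_length`, `subject_length`, `identity`; vectorised over rows of a
#'   data.frame.
#' @return Logical vector.
#' @export
is_matched <- function(hit) {
  if (any(hit$aln_length < 1L) || any(hit$query_length < 1L) ||
      any(hit$subject_length < 1L))
    stop("alignment and sequence lengths must be >= 1")
  if (any(hit$identity < 0 | hit$identity > 1))
    stop("identity must be a fraction in [0, 1]")
  (hit$aln_length / hit$query_length > 0.95) &
    (hit$identity >= 0.80) &
    (hit$subject_length > hit$query_length)
}

#' Update presence from matched alignment hits
#'
#' For each matched hit whose subject library's category is not already set
#' on the query TF's presence row, the bit is set and a change-log entry
#' recorded. Bits are never cleared; re-applying the same hits is a no-op.
#' Recompute specificity flags afterwards with [classify_specific()].
#'
#' @param tf_records TF records (`tf_id`, `source_est_id`); hits are keyed
#'   by query EST id.
#' @param presence Presence matrix from [build_presence()].
#' @param hits Alignment-hit data.frame (see [local_align()] /
#'   [read_hit_table()]); rows failing [is_matched()] are ignored.
#' @param library_categories Named vector `library_id -> category` for this
#'   axis.
#' @param axis `"stage"` or `"tissue"` (recorded in the change log).
#' @return List with `presence` (updated matrix) and `changes` (data.frame
#'   `tf_id`, `axis`, `category`, `subject_id`, `source` = "blast_update").
#' @export
update_from_matches <- function(tf_records, presence, hits,
                                library_categories,
                                axis = c("stage", "tissue")) {
  axis <- match.arg(axis)
  changes <- .empty_changes()
  if (nrow(hits) == 0L) return(list(presence = presence, changes = changes))
  tf_of_est <- stats::setNames(tf_records$tf_id, tf_records$source_est_id)
  keep <- is_matched(hits)
  h <- hits[keep, , drop = FALSE]
  for (i in seq_len(nrow(h))) {
    tf <- tf_of_est[h$query_id[i]]
    if (is.na(tf)) stop("hit references unknown query TF EST: ", h$query_id[i])
    cat <- library_categories[h$subject_library_id[i]]
    if (is.na(cat)) stop("subject library without category: ",
                         h$subject_library_id[i])
    if (presence[tf, cat] == 0L) {
      presence[tf, cat] <- 1L
      changes <- rbind(changes, data.frame(
        tf_id = unname(tf), axis = axis, category = unname(cat),
        subject_id = h$subject_id[i], source = "blast_update",
        stringsAsFactors = FALSE))
    }
  }
  list(presence = presence, changes = changes)
}

#' Recover annotations from filtered-out sequences
#'
#' Each clustered-away EST is translated and scanned; if it is itself a TF
#' (any hit below the E-value threshold) and its cluster representative is
#' an identified TF, the filtered EST's library category is OR-ed into the
#' representative's presence row. Additions are logged.
#'
#' @param filtered_ests data.frame of removed ESTs (`id`, `sequence`,
#'   `library_id`).
#' @param cl_map Named vector `member est id -> representative est id`
#'   (see [cluster_map()]).
#' @param tf_records TF records; representatives are matched on
#'   `source_est_id`.
#' @param profiles Calibrated profiles for the scan.
#' @param presence Presence matrix to update.
#' @param library_categories Named vector `library_id -> category`.
#' @param axis `"stage"` or `"tissue"`.
#' @param min_aa,e_max Translation and scan parameters.
#' @return List with `presence`, `changes` (source = "filtered_recovery"),
#'   and `n_filtered_tfs` (how many filtered ESTs were themselves TFs).
#' @export
recover_filtered <- function(filtered_ests, cl_map, tf_records, profiles,
                             presence, library_categories,
                             axis = c("stage", "tissue"),
                             min_aa = 30L, e_max = 0.01) {
  axis <- match.arg(axis)
  changes <- .empty_changes()
  if (nrow(filtered_ests) == 0L)
    return(list(presence = presence, changes = changes, n_filtered_tfs = 0L))
  unknown <- setdiff(filtered_ests$id, names(cl_map))
  if (length(unknown))
    stop("filtered EST without representative: ",
         paste(unknown, collapse = ", "))
  prots <- translate_corpus(filtered_ests, min_aa = min_aa)
  hits <- scan_proteins(prots, profiles, e_max = e_max)
  tf_ests <- unique(prots$source_id[prots$protein_id %in% hits$protein_id])
  tf_of_est <- stats::setNames(tf_records$tf_id, tf_records$source_est_id)
  for (est in tf_ests) {
    rep_est <- cl_map[est]
    tf <- tf_of_est[rep_est]
    if (is.na(tf)) next  # representative was not an identified TF
    lib <- filtered_ests$library_id[filtered_ests$id == est]
    cat <- library_categories[lib]
    if (is.na(cat)) stop("library without category: ", lib)
    if (presence[tf, cat] == 0L) {
      presence[tf, cat] <- 1L
      changes <- rbind(changes, data.frame(
        tf_id = unname(tf), axis = axis, category = unname(cat),
        subject_id = est, source = "filtered_recovery",
        stringsAsFactors = FALSE))
    }
  }
  list(presence = presence, changes = changes,
       n_filtered_tfs = length(tf_ests))
}

.empty_changes <- function() {
  data.frame(tf_id = character(), axis = character(), category = character(),
             subject_id = character(), source = character(),
             stringsAsFactors = FALSE)
}

#' Replay a change log onto a presence matrix
#'
#' Applying the logged additions to the initial matrix reproduces the final
#' matrix exactly.
#'
#' @param presence Initial presence matrix.
#' @param changes Change-log data.frame (`tf_id`, `category`).
#' @return Updated matrix.
#' @export
replay_changes <- function(presence, changes) {
  for (i in seq_len(nrow(changes)))
    presence[changes$tf_id[i], changes$category[i]] <- 1L
  presence
}

#' Read a 12-column tabular alignment hit table
#'
#' Standard tabular hit format (query id, subject id, percent identity,
#' alignment length, mismatches, gap opens, q.start, q.end, s.start, s.end,
#' e-value, bit score) plus a sidecar TSV mapping `subject_id` to
#' `library_id`. Percent identities are normalised to fractions; query and
#' subject lengths must be supplied since the tabular format lacks them.
#'
#' @param path Hit table path (no header).
#' @param sidecar_path TSV with header `subject_id<TAB>library_id`.
#' @param query_lengths,subject_lengths Named numeric vectors id -> length.
#' @return Alignment-hit data.frame compatible with
#'   [update_from_matches()].
#' @export
read_hit_table <- function(path, sidecar_path, query_lengths,
                           subject_lengths) {
  cols <- c("query_id", "subject_id", "pident", "aln_length", "mismatches",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  x <- read.delim(path, header = FALSE, col.names = cols,
                  colClasses = c("character", "character", rep("numeric", 10)))
  side <- read.delim(sidecar_path, colClasses = "character")
  if (!all(c("subject_id", "library_id") %in% names(side)))
    stop("sidecar must have columns subject_id, library_id")
  lib <- stats::setNames(side$library_id, side$subject_id)[x$subject_id]
  if (any(is.na(lib))) stop("subject(s) missing from sidecar mapping")
  identity <- x$pident
  if (any(identity > 1)) identity <- identity / 100
  ql <- query_lengths[x$query_id]
  sl <- subject_lengths[x$subject_id]
  if (any(is.na(ql)) || any(is.na(sl)))
    stop("missing query/subject length for hit table entries")
  data.frame(query_id = x$query_id, subject_id = x$subject_id,
             identity = identity, aln_length = x$aln_length,
             query_length = unname(ql), subject_length = unname(sl),
             subject_library_id = unname(lib), score = x$bitscore,
             stringsAsFactors = FALSE)
}

#' Align putative specific TFs against a validation EST database
#'
#' Internal stand-in for the external alignment search: every (query,
#' subject) pair is locally aligned with [local_align()] and all hits are
#' returned; filtering is left to [is_matched()].
#'
#' @param query_ests data.frame of query ESTs (`id`, `sequence`).
#' @param db_ests data.frame of database ESTs (`id`, `sequence`,
#'   `library_id`).
#' @return Alignment-hit data.frame.
#' @export
align_against_db <- function(query_ests, db_ests) {
  rows <- list()
  for (i in seq_len(nrow(query_ests))) {
    for (j in seq_len(nrow(db_ests))) {
      rows[[length(rows) + 1L]] <- local_align(
        query_ests$sequence[i], db_ests$sequence[j],
        query_id = query_ests$id[i], subject_id = db_ests$id[j],
        subject_library_id = db_ests$library_id[j])
    }
  }
  if (!length(rows))
    return(local_align("A", "A")[0, , drop = FALSE])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
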