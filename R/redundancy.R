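# Greedy identity clustering (cd-hit stand-in) and cross-set redundancy
# tabulation. Identity semantics live in alignment.R (denominator = shorter
# sequence, best local alignment).

.kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Greedy identity clustering of a sequence set
#'
#' cd-hit-style incremental clustering: sequences are processed in order of
#' decreasing length (ties by input order); each sequence joins the first
#' existing cluster whose representative has identity >= `threshold` to it
#' (identity per [pairwise_identity()]), otherwise it founds a new cluster.
#' Because processing is length-descending, every representative is the
#' longest sequence of its cluster.
#'
#' A shared-k-mer prefilter (`word_size`) may skip representative comparisons
#' for pairs sharing no k-mer; it is applied only when `threshold >= 0.95`
#' and both sequences are long enough that the skip is identity-safe
#' (identity >= 0.95 over the shorter sequence forces a shared word of
#' length 8 or 5). Correctness never depends on the prefilter.
#'
#' @param records Named character vector of sequences (names = ids).
#' @param threshold Identity threshold in (0, 1\].
#' @param word_size Prefilter word length; defaults to 8 for nucleotide and
#'   5 for protein.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param use_prefilter Disable to force full comparisons (used by tests).
#' @return List of clusters; each is a list with `representative_id`,
#'   `member_ids` (excluding the representative, in joining order) and
#'   `threshold`.
#' @export
greedy_cluster <- function(records, threshold, word_size = NULL,
                           alphabet = c("nucleotide", "protein"),
                           use_prefilter = TRUE) {
  alphabet <- match.arg(alphabet)
  stopifnot(threshold > 0, threshold <= 1)
  if (is.null(word_size)) word_size <- if (alphabet == "nucleotide") 8L else 5L
  stopifnot(word_size >= 1L)
  if (length(records) == 0L) return(list())
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("records must be a named character vector")
  if (anyDuplicated(names(records))) stop("duplicate sequence ids")
  if (any(!nzchar(records))) stop("empty sequence in input")

  ord <- order(-nchar(records), seq_along(records))
  ids <- names(records)[ord]
  seqs <- unname(records[ord])

  prefilter_on <- use_prefilter && threshold >= 0.95
  kmers <- if (prefilter_on) lapply(seqs, .kmer_set, k = word_size) else NULL

  reps <- integer(0)              # indices (into ord) of representatives
  members <- list()
  for (i in seq_along(seqs)) {
    cand <- reps
    if (prefilter_on && length(cand) && nchar(seqs[i]) >= 2L * word_size) {
      # prefilter is only safe when both sequences are long enough that a
      # >= 0.95 identity match must share a word of length word_size
      keep <- vapply(cand, function(ri) {
        nchar(seqs[ri]) < 2L * word_size ||
          any(kmers[[i]] %in% kmers[[ri]])
      }, TRUE)
      cand <- cand[keep]
    }
    placed <- FALSE
    if (length(cand)) {
      ident <- .batch_identity(seqs[cand], seqs[i], alphabet)
      hit <- which(ident >= threshold)
      if (length(hit)) {
        ci <- match(cand[hit[1L]], reps)   # first cluster in founding order
        members[[ci]] <- c(members[[ci]], ids[i])
        placed <- TRUE
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      members[[length(reps)]] <- character()
    }
  }
  lapply(seq_along(reps), function(ci) {
    list(representative_id = ids[reps[ci]],
         member_ids = members[[ci]],
         threshold = threshold)
  })
}

#' Number of redundant sequences in a clustering
#'
#' Redundant sequences are the non-representative cluster members, i.e. the
#' total number of sequences minus the number of clusters.
#'
#' @param clusters List of clusters from one [greedy_cluster()] run.
#' @return Non-negative integer count.
#' @export
redundant_count <- function(clusters) {
  sum(vapply(clusters, function(cl) length(cl$member_ids), 0L))
}

#' Member-to-representative map of a clustering
#'
#' @param clusters List of clusters from [greedy_cluster()].
#' @return Named character vector mapping each non-representative member id
#'   to its representative id.
#' @export
cluster_map <- function(clusters) {
  out <- unlist(lapply(clusters, function(cl) {
    if (length(cl$member_ids) == 0L) return(character())
    stats::setNames(rep(cl$representative_id, length(cl$member_ids)),
                    cl$member_ids)
  }))
  if (is.null(out)) character() else out
}

#' Cross-set redundancy report at multiple identity thresholds
#'
#' For a single-set combination the count is [redundant_count()] of
#' clustering that set alone; for a multi-set combination the pooled
#' sequences are clustered and the count is the number of sequences that
#' belong to clusters spanning two or more source sets. Counts are
#' non-increasing in the threshold for a fixed combination.
#'
#' @param sets Named list of named character vectors (set name -> sequences).
#' @param thresholds Numeric vector of identity thresholds in (0, 1\].
#' @param combinations List of character vectors of set names; default: every
#'   single set, every pair, and (when > 2 sets) the full combination.
#' @param alphabet Sequence alphabet.
#' @return A data.frame report with columns `combination`, `threshold`,
#'   `redundant_count`.
#' @export
cross_set_redundancy <- function(sets, thresholds = c(0.85, 0.90, 0.95, 1.00),
                                 combinations = NULL,
                                 alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  stopifnot(length(sets) >= 1L, !is.null(names(sets)))
  if (is.null(combinations)) {
    nm <- names(sets)
    combinations <- as.list(nm)
    if (length(nm) >= 2L)
      combinations <- c(combinations,
                        utils::combn(nm, 2L, simplify = FALSE))
    if (length(nm) > 2L) combinations <- c(combinations, list(nm))
  }
  for (cb in combinations) {
    unknown <- setdiff(cb, names(sets))
    if (length(unknown))
      stop("unknown set name in combination: ", paste(unknown, collapse = ", "))
  }
  rows <- list()
  for (cb in combinations) {
    pooled <- unlist(unname(sets[cb]))
    source_of <- rep(cb, vapply(sets[cb], length, 0L))
    names(source_of) <- names(pooled)
    for (th in sort(thresholds)) {
      cl <- greedy_cluster(pooled, th, alphabet = alphabet)
      n <- if (length(cb) == 1L) {
        redundant_count(cl)
      } else {
        sum(vapply(cl, function(x) {
          ids <- c(x$representative_id, x$member_ids)
          if (length(unique(source_of[ids])) >= 2L) length(ids) else 0L
        }, 0L))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        combination = paste(cb, collapse = "+"),
        threshold = th, redundant_count = n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write clusters in a cd-hit .clstr-like text format
#'
#' @param clusters List of clusters from [greedy_cluster()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_clstr <- function(clusters, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    writeLines(sprintf(">Cluster %d", i - 1L), con)
    ids <- c(cl$representative_id, cl$member_ids)
    marks <- c("*", rep(sprintf("at >=%.2f", cl$threshold),
                        length(cl$member_ids)))
    writeLines(sprintf("%d\t>%s... %s", seq_along(ids) - 1L, ids, marks), con)
  }
  invisible(path)
}
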