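# Local alignment plumbing shared by the redundancy and validation modules.
# Alignment itself goes through Biostrings::pairwiseAlignment; this file owns
# the identity conventions (denominator, ambiguity handling) built on top.

.subst_matrix <- function(alphabet, match = 1L, mismatch = -2L) {
  letters <- if (alphabet == "nucleotide") c("A", "C", "G", "T", "N")
             else c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  # ambiguity codes never score as matches
  amb <- if (alphabet == "nucleotide") "N" else "X"
  m[amb, amb] <- mismatch
  m
}

# Count identical aligned positions from the two gapped alignment strings,
# excluding ambiguity characters (N/X never count as identical).
.aligned_matches <- function(pat, sub, alphabet) {
  p <- strsplit(pat, "")[[1]]
  s <- strsplit(sub, "")[[1]]
  amb <- if (alphabet == "nucleotide") "N" else "X"
  sum(p == s & p != "-" & p != amb)
}

.local_pair <- function(a, b, alphabet, match = 1, mismatch = -2,
                        gap_open = 2, gap_extend = 1) {
  mat <- .subst_matrix(alphabet, match, mismatch)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  list(
    score = Biostrings::score(aln),
    aln_length = nchar(pat),
    n_ident = .aligned_matches(pat, sub, alphabet),
    q_start = Biostrings::start(Biostrings::pattern(aln)),
    q_end = Biostrings::end(Biostrings::pattern(aln)),
    s_start = Biostrings::start(Biostrings::subject(aln)),
    s_end = Biostrings::end(Biostrings::subject(aln)),
    pattern = pat, subject = sub
  )
}

# Batched identity of one query against many references (one S4 alignment
# call instead of one per pair). Falls back to the exact per-pair path when
# ambiguity characters are present, since N=N / X=X must not count.
.batch_identity <- function(refs, query, alphabet, match = 1, mismatch = -2,
                            gap_open = 2, gap_extend = 1) {
  if (!length(refs)) return(numeric())
  amb <- if (alphabet == "nucleotide") "N" else "X"
  mat <- .subst_matrix(alphabet, match, mismatch)
  cls <- Biostrings::BStringSet
  aln <- Biostrings::pairwiseAlignment(
    cls(refs), Biostrings::BString(query),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  nid <- Biostrings::nmatch(aln)
  has_amb <- grepl(amb, refs, fixed = TRUE) | grepl(amb, query, fixed = TRUE)
  if (any(has_amb)) {
    pat <- as.character(Biostrings::alignedPattern(aln))
    sub <- as.character(Biostrings::alignedSubject(aln))
    for (i in which(has_amb))
      nid[i] <- .aligned_matches(pat[i], sub[i], alphabet)
  }
  pmin(1, nid / pmin(nchar(refs), nchar(query)))
}

#' Pairwise identity of two sequences
#'
#' cd-hit-convention identity: identical positions in the best local
#' alignment divided by the length of the shorter sequence. Symmetric and in
#' \[0, 1\]. Ambiguity characters (`N` for nucleotide, `X` for protein) never
#' count as identical positions.
#'
#' @param a,b Non-empty sequences over the same alphabet.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  r <- .local_pair(a, b, alphabet, match = 1, mismatch = -2,
                   gap_open = 2, gap_extend = 1)
  min(1, r$n_ident / min(nchar(a), nchar(b)))
}

#' Smith-Waterman local alignment of two nucleotide sequences
#'
#' Best local alignment under match +1 / mismatch -2 and affine gaps (a gap
#' of length k costs `gap_open + k * gap_extend`). Identity here is the
#' alignment-level convention used by tabular hit reports: identical
#' positions divided by alignment length (gaps included in the denominator).
#'
#' @param a Query nucleotide sequence (non-empty).
#' @param b Subject nucleotide sequence (non-empty).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @param query_id,subject_id,subject_library_id Carried into the hit record.
#' @return A one-row data.frame alignment hit: `query_id`, `subject_id`,
#'   `identity`, `aln_length`, `query_length`, `subject_length`,
#'   `subject_library_id`, `score`.
#' @export
local_align <- function(a, b, match = 1, mismatch = -2, gap_open = 2,
                        gap_extend = 1, query_id = "query",
                        subject_id = "subject", subject_library_id = NA_character_) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  r <- .local_pair(toupper(a), toupper(b), "nucleotide", match, mismatch,
                   gap_open, gap_extend)
  data.frame(
    query_id = query_id, subject_id = subject_id,
    identity = if (r$aln_length > 0) r$n_ident / r$aln_length else 0,
    aln_length = r$aln_length,
    query_length = nchar(a), subject_length = nchar(b),
    subject_library_id = subject_library_id,
    score = r$score,
    stringsAsFactors = FALSE
  )
}
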