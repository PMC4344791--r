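# Six-frame ORF search (framefinder stand-in). ESTs are fragments, so a Met
# start is not required: candidates are maximal stop-free stretches of the
# six conceptual translations. Codons containing N translate to X.

# codon lookup built from the standard genetic code; codons containing N
# (or any non-ACGT character) fall through to X
.GENCODE <- Biostrings::GENETIC_CODE

.translate_frame <- function(dna, offset) {
  n <- nchar(dna)
  usable <- n - offset
  usable <- usable - (usable %% 3L)
  if (usable < 3L) return("")
  starts <- seq(offset + 1L, offset + usable, by = 3L)
  aa <- .GENCODE[substring(dna, starts, starts + 2L)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

.revcomp <- function(dna) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", dna), "")[[1]]), collapse = "")
}

.stretches <- function(aa, min_aa) {
  # maximal runs of non-stop residues, as (aa_start, aa_end) 1-based closed
  if (!nzchar(aa)) return(NULL)
  r <- rle(strsplit(aa, "")[[1]] == "*")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !r$values & r$lengths >= min_aa
  if (!any(keep)) return(NULL)
  cbind(start = starts[keep], end = ends[keep])
}

#' Six-frame ORF candidates of an EST
#'
#' Returns every maximal stop-free stretch of at least `min_aa` residues
#' across the six reading frames, translated with the standard genetic code
#' (fuzzy codons become `X`). Coordinates are 0-based half-open on the
#' forward strand; frames are `+1,+2,+3` (forward) and `-1,-2,-3` (reverse
#' complement).
#'
#' @param sequence Nucleotide sequence (length >= 3) or a one-row EST record
#'   (list/data.frame with `id` and `sequence`).
#' @param min_aa Minimum ORF length in residues (default 30).
#' @param id Sequence id used when `sequence` is a bare string.
#' @return data.frame with columns `source_id`, `protein`, `frame`,
#'   `nt_start`, `nt_end`; zero rows when nothing qualifies.
#' @export
six_frame_orfs <- function(sequence, min_aa = 30L, id = "seq") {
  if (is.list(sequence)) {
    id <- sequence$id
    sequence <- sequence$sequence
  }
  sequence <- toupper(sequence)
  if (nchar(sequence) < 3L) stop("sequence shorter than one codon")
  L <- nchar(sequence)
  rc <- .revcomp(sequence)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else rc
    for (off in 0:2) {
      aa <- .translate_frame(s, off)
      st <- .stretches(aa, min_aa)
      if (is.null(st)) next
      for (k in seq_len(nrow(st))) {
        a0 <- off + 3L * (st[k, "start"] - 1L)   # 0-based on this strand
        a1 <- off + 3L * st[k, "end"]
        if (strand == "+") {
          nt_start <- a0; nt_end <- a1; frame <- off + 1L
        } else {
          nt_start <- L - a1; nt_end <- L - a0; frame <- -(off + 1L)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          source_id = id,
          protein = substring(aa, st[k, "start"], st[k, "end"]),
          frame = frame, nt_start = nt_start, nt_end = nt_end,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(source_id = character(), protein = character(),
                      frame = integer(), nt_start = integer(),
                      nt_end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Best protein candidate of an EST
#'
#' The longest six-frame ORF; ties are broken by frame order
#' `+1, +2, +3, -1, -2, -3`, then by smaller `nt_start`.
#'
#' @inheritParams six_frame_orfs
#' @return One-row data.frame as in [six_frame_orfs()], or `NULL` when no
#'   ORF reaches `min_aa`.
#' @export
best_protein <- function(sequence, min_aa = 30L, id = "seq") {
  cands <- six_frame_orfs(sequence, min_aa = min_aa, id = id)
  if (nrow(cands) == 0L) return(NULL)
  frame_rank <- match(cands$frame, c(1L, 2L, 3L, -1L, -2L, -3L))
  ord <- order(-nchar(cands$protein), frame_rank, cands$nt_start)
  cands[ord[1L], , drop = FALSE]
}

#' Translate a corpus to its best proteins
#'
#' Applies [best_protein()] to every EST; ESTs with no qualifying ORF are
#' dropped.
#'
#' @param ests data.frame with `id` and `sequence` columns.
#' @param min_aa Minimum ORF length in residues.
#' @return data.frame of protein candidates with a `protein_id` column
#'   (`source_id|frame|start-end`).
#' @export
translate_corpus <- function(ests, min_aa = 30L) {
  rows <- lapply(seq_len(nrow(ests)), function(i) {
    best_protein(ests$sequence[i], min_aa = min_aa, id = ests$id[i])
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(source_id = character(), protein = character(),
                      frame = integer(), nt_start = integer(),
                      nt_end = integer(), protein_id = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$protein_id <- sprintf("%s|%+d|%d-%d", out$source_id, out$frame,
                            out$nt_start, out$nt_end)
  out
}

#' Write protein candidates as FASTA
#'
#' Headers follow `source_id|frame|start-end` with 0-based half-open
#' forward-strand coordinates.
#'
#' @param proteins data.frame from [translate_corpus()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_protein_fasta <- function(proteins, path) {
  x <- Biostrings::AAStringSet(proteins$protein)
  names(x) <- proteins$protein_id
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
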