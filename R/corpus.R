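#' @importFrom methods is
#' @importFrom stats rbinom runif sd var
#' @importFrom utils read.delim write.table head tail
NULL

# Category vocabularies. The presence-vector column orders below follow the
# per-TF table layout (stage: dormant seed .. vegetative, catch-all last;
# tissue: crown .. stem, catch-all last), which differs from the enumeration
# order used for raw label mapping.

#' Developmental-stage categories
#'
#' Seven developmental-stage categories an EST library can be assigned to.
#' `unclear` is the catch-all absorbing unknown, mixed and unclassified
#' libraries.
#'
#' @return Character vector of the 7 stage category names.
#' @export
stage_categories <- function() {
  c("dormant_seed", "germinating_seed", "seedling", "vegetative",
    "reproductive", "ripening", "unclear")
}

#' Tissue categories
#'
#' Seven tissue categories an EST library can be assigned to. `other` is the
#' catch-all (callus, cell culture, whole plant, mixed or unspecified tissue).
#'
#' @return Character vector of the 7 tissue category names.
#' @export
tissue_categories <- function() {
  c("crown", "flower", "leaf", "root", "seed", "stem", "other")
}

#' Presence-vector column order for an axis
#'
#' The order in which the 7 categories appear as columns of a presence
#' matrix / per-TF record: informative categories first (alphabetical for
#' stages as in the per-TF tables), catch-all last.
#'
#' @param axis `"stage"` or `"tissue"`.
#' @return Character vector of 7 category names; the 7th is the catch-all.
#' @export
presence_order <- function(axis = c("stage", "tissue")) {
  axis <- match.arg(axis)
  if (axis == "stage") {
    c("dormant_seed", "germinating_seed", "reproductive", "ripening",
      "seedling", "vegetative", "unclear")
  } else {
    c("crown", "flower", "leaf", "root", "seed", "stem", "other")
  }
}

#' Catch-all category of an axis
#' @param axis `"stage"` or `"tissue"`.
#' @return `"unclear"` for stage, `"other"` for tissue.
#' @export
catchall_category <- function(axis = c("stage", "tissue")) {
  if (match.arg(axis) == "stage") "unclear" else "other"
}

.normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[ \t]+", " ", x)
}

.default_stage_map <- c(
  "dormant seed"      = "dormant_seed",
  "germinating seed"  = "germinating_seed",
  "seedling"          = "seedling",
  "vegetative"        = "vegetative",
  "reproductive"      = "reproductive",
  "ripening"          = "ripening",
  "unknown developmental stage" = "unclear",
  "mixed"             = "unclear",
  "not yet classified" = "unclear",
  "unclear"           = "unclear"
)

.default_tissue_map <- c(
  "crown"          = "crown",
  "flower"         = "flower",
  "inflorescence"  = "flower",
  "leaf"           = "leaf",
  "sheath"         = "leaf",
  "root"           = "root",
  "seed"           = "seed",
  "stem"           = "stem",
  "callus"         = "other",
  "cell culture"   = "other",
  "whole plant"    = "other",
  "mixed tissue"   = "other",
  "not yet classified" = "other",
  "unspecified"    = "other",
  "other"          = "other"
)

#' Map a raw library stage label to a stage category
#'
#' Matching is exact-keyword after lower-casing and whitespace normalisation
#' (no substring matching). Unrecognised, empty or explicitly unclassified
#' labels fall into the `unclear` catch-all. The function is total: every
#' string maps to exactly one category.
#'
#' @param raw_stage_label Character vector of raw library labels.
#' @param overrides Named character vector mapping extra keywords (raw label,
#'   normalised or not) to stage categories; takes precedence over defaults.
#' @return Character vector of stage categories, same length as the input.
#' @export
map_stage <- function(raw_stage_label, overrides = character()) {
  .map_label(raw_stage_label, .default_stage_map, overrides,
             valid = stage_categories(), catchall = "unclear")
}

#' Map a raw library tissue label to a tissue category
#'
#' Exact-keyword matching after normalisation; `inflorescence` folds into
#' `flower`, `sheath` into `leaf`; callus / cell culture / whole plant /
#' mixed / unspecified and anything unrecognised fall into `other`.
#'
#' @inheritParams map_stage
#' @return Character vector of tissue categories.
#' @export
map_tissue <- function(raw_tissue_label, overrides = character()) {
  .map_label(raw_tissue_label, .default_tissue_map, overrides,
             valid = tissue_categories(), catchall = "other")
}

.map_label <- function(labels, default_map, overrides, valid, catchall) {
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("overrides must be a named character vector")
    bad <- setdiff(unname(overrides), valid)
    if (length(bad))
      stop("override targets outside the category set: ",
           paste(bad, collapse = ", "))
    names(overrides) <- .normalize_label(names(overrides))
    default_map <- c(overrides, default_map[setdiff(names(default_map),
                                                    names(overrides))])
  }
  key <- .normalize_label(labels)
  out <- unname(default_map[key])
  out[is.na(out)] <- catchall
  out
}

#' Load an EST corpus
#'
#' Reads nucleotide ESTs from a FASTA file and their library annotations from
#' a 3-column TSV (`library_id`, `stage_label`, `tissue_label`). Every EST id
#' must be unique; sequences are restricted to the alphabet `A,C,G,T,N`
#' (anything else is an error, not silently sanitised); every EST must
#' reference a library present in the table. The EST's library is encoded in
#' its FASTA header as `id|library_id` (or supplied via `library_of`).
#'
#' @param fasta_path Path to a nucleotide FASTA file. Headers are either
#'   `id|library_id` or a bare `id` (then `library_of` must cover it).
#' @param library_table_path Path to the annotation TSV with header
#'   `library_id<TAB>stage_label<TAB>tissue_label`.
#' @param library_of Optional named character vector `id -> library_id` used
#'   for headers lacking the `|library_id` suffix.
#' @return A list with `ests` (data.frame: id, sequence, library_id) and
#'   `libraries` (data.frame: library_id, stage_label, tissue_label).
#' @export
load_corpus <- function(fasta_path, library_table_path, library_of = NULL) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(library_table_path))
    stop("library table not found: ", library_table_path)
  libs <- read.delim(library_table_path, colClasses = "character",
                     check.names = FALSE)
  need <- c("library_id", "stage_label", "tissue_label")
  if (!all(need %in% names(libs)))
    stop("library table must have columns: ", paste(need, collapse = ", "))
  libs <- libs[, need, drop = FALSE]
  if (anyDuplicated(libs$library_id))
    stop("duplicate library_id in annotation table")

  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L) {
    ests <- data.frame(id = character(), sequence = character(),
                       library_id = character(), stringsAsFactors = FALSE)
    return(list(ests = ests, libraries = libs))
  }
  hdr <- names(seqs)
  parts <- strsplit(hdr, "|", fixed = TRUE)
  id <- vapply(parts, `[`, "", 1L)
  lib <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, "")
  if (any(is.na(lib))) {
    if (is.null(library_of))
      stop("FASTA headers lack |library_id and no library_of mapping given")
    lib[is.na(lib)] <- unname(library_of[id[is.na(lib)]])
    if (any(is.na(lib))) stop("no library mapping for EST(s): ",
                              paste(head(id[is.na(lib)]), collapse = ", "))
  }
  if (anyDuplicated(id)) stop("duplicate sequence id(s) in FASTA: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  sequence <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad))
    stop("sequence(s) with characters outside {A,C,G,T,N}: ",
         paste(head(id[bad]), collapse = ", "))
  if (any(nchar(sequence) < 1L)) stop("empty sequence(s) in FASTA")
  unknown <- setdiff(lib, libs$library_id)
  if (length(unknown))
    stop("EST(s) reference unknown library: ", paste(unknown, collapse = ", "))
  ests <- data.frame(id = unname(id), sequence = unname(sequence),
                     library_id = unname(lib), stringsAsFactors = FALSE)
  list(ests = ests, libraries = libs)
}

#' Write an EST corpus
#'
#' Inverse of [load_corpus()]: writes `id|library_id` FASTA plus the library
#' annotation TSV (UTF-8, LF). Round-trips ids, sequences and library
#' assignments exactly.
#'
#' @param corpus List with `ests` and `libraries` as returned by
#'   [load_corpus()] or [generate_corpus()].
#' @param fasta_path,library_table_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_corpus <- function(corpus, fasta_path, library_table_path) {
  ests <- corpus$ests
  x <- Biostrings::DNAStringSet(ests$sequence)
  names(x) <- paste0(ests$id, "|", ests$library_id)
  Biostrings::writeXStringSet(x, fasta_path, width = 70L)
  write.table(corpus$libraries, library_table_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, library_table_path))
}

#' Categorise a library table
#'
#' Applies [map_stage()] and [map_tissue()] to the raw labels of a library
#' annotation table.
#'
#' @param libraries data.frame with `library_id`, `stage_label`,
#'   `tissue_label`.
#' @param stage_overrides,tissue_overrides Passed to the mapping functions.
#' @return The table with `stage_category` and `tissue_category` columns
#'   appended.
#' @export
categorize_libraries <- function(libraries, stage_overrides = character(),
                                 tissue_overrides = character()) {
  libraries$stage_category <- map_stage(libraries$stage_label, stage_overrides)
  libraries$tissue_category <- map_tissue(libraries$tissue_label, tissue_overrides)
  libraries
}
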