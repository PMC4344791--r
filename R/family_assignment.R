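# Family rules (required/forbidden DNA-binding domains) and the bookkeeping
# that turns domain hits into exactly one family call per protein.

#' Evaluate a family rule against a protein's domain hits
#'
#' `required` is a list of domain-name sets combined as AND over sets and OR
#' within a set; `forbidden` is a flat set. The rule holds iff every
#' required set has at least one member among the hits and no forbidden
#' domain is hit.
#'
#' @param hits_for_protein Character vector of domain (family profile) names
#'   hit by the protein.
#' @param rule List with `family`, `required` (list of character vectors,
#'   non-empty) and `forbidden` (character vector).
#' @return Logical scalar.
#' @export
evaluate_rule <- function(hits_for_protein, rule) {
  if (!length(rule$required)) stop("rule has no required domain sets")
  if (length(intersect(unlist(rule$required), rule$forbidden)))
    stop("rule required and forbidden sets overlap")
  all(vapply(rule$required,
             function(set) any(set %in% hits_for_protein), TRUE)) &&
    !any(rule$forbidden %in% hits_for_protein)
}

#' Candidate families per protein
#'
#' For every protein, lists all families whose rule evaluates true on the
#' protein's hit set, each tagged with the protein's best bit score among
#' the hits to that family's required domains.
#'
#' @param hits Domain-hit data.frame from [scan_proteins()].
#' @param rules List of family rules (unique family names).
#' @return data.frame `protein_id`, `family`, `bit_score`, `rule_size`
#'   (total number of domain names in the rule's required sets).
#' @export
assign_families <- function(hits, rules) {
  fams <- vapply(rules, `[[`, "", "family")
  if (anyDuplicated(fams)) stop("duplicate family names in rules")
  empty <- data.frame(protein_id = character(), family = character(),
                      bit_score = numeric(), rule_size = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  rows <- list()
  for (pid in unique(hits$protein_id)) {
    h <- hits[hits$protein_id == pid, , drop = FALSE]
    for (rule in rules) {
      if (evaluate_rule(h$family, rule)) {
        req <- unlist(rule$required)
        bs <- max(h$bit_score[h$family %in% req])
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = pid, family = rule$family, bit_score = bs,
          rule_size = length(req), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Resolve multi-family candidates to one family per protein
#'
#' Highest diagnostic bit score wins; ties go to the more specific rule
#' (fewer total rule domains); remaining ties to the lexicographically
#' smallest family name. Deterministic.
#'
#' @param candidates data.frame from [assign_families()].
#' @return data.frame `protein_id`, `family`, `bit_score`, one row per
#'   protein.
#' @export
resolve_multi_family <- function(candidates) {
  if (nrow(candidates) == 0L)
    return(data.frame(protein_id = character(), family = character(),
                      bit_score = numeric(), stringsAsFactors = FALSE))
  ord <- order(candidates$protein_id, -candidates$bit_score,
               candidates$rule_size, candidates$family)
  x <- candidates[ord, , drop = FALSE]
  x <- x[!duplicated(x$protein_id), c("protein_id", "family", "bit_score")]
  rownames(x) <- NULL
  x
}

#' Drop families with zero assigned TFs
#'
#' @param assignments data.frame with a `family` column.
#' @param declared_families Character vector of declared family names.
#' @return List with `retained` (families with >= 1 TF, in declared order)
#'   and `removed`.
#' @export
drop_empty_families <- function(assignments, declared_families) {
  populated <- unique(assignments$family)
  retained <- declared_families[declared_families %in% populated]
  removed <- setdiff(declared_families, retained)
  if (length(removed))
    message("removed ", length(removed), " empty families: ",
            paste(removed, collapse = ", "))
  list(retained = retained, removed = removed)
}

#' Mint sequential TF identifiers
#'
#' Assigns zero-padded 5-digit ids (`TaTF00001`, ...) in (family, source
#' EST id) sort order; stable across reruns on identical input.
#'
#' @param assignments data.frame with `protein_id`, `family`, `bit_score`.
#' @param proteins data.frame from [translate_corpus()] (maps protein ids to
#'   source EST ids).
#' @param prefix Id prefix (default `"TaTF"`).
#' @return TF-record data.frame: `tf_id`, `family`, `source_est_id`,
#'   `protein_id`, `bit_score`.
#' @export
mint_tf_ids <- function(assignments, proteins, prefix = "TaTF") {
  if (nrow(assignments) == 0L)
    return(data.frame(tf_id = character(), family = character(),
                      source_est_id = character(), protein_id = character(),
                      bit_score = numeric(), stringsAsFactors = FALSE))
  src <- proteins$source_id[match(assignments$protein_id, proteins$protein_id)]
  if (any(is.na(src))) stop("assignment references unknown protein_id")
  ord <- order(assignments$family, src)
  x <- assignments[ord, , drop = FALSE]
  if (nrow(x) > 99999L) stop("TF id space overflow (> 99999 records)")
  data.frame(
    tf_id = sprintf("%s%05d", prefix, seq_len(nrow(x))),
    family = x$family, source_est_id = src[ord],
    protein_id = x$protein_id, bit_score = x$bit_score,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Read family rules from JSON
#'
#' Expects a JSON list of `{family, required: [[...]], forbidden: [...]}`.
#'
#' @param path Path to the rules JSON file.
#' @return List of family rules.
#' @export
read_family_rules <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    list(family = r$family,
         required = lapply(r$required, function(s) unlist(s, use.names = FALSE)),
         forbidden = unlist(r$forbidden, use.names = FALSE) %||% character())
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write family rules as JSON
#' @param rules List of family rules.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_family_rules <- function(rules, path) {
  jsonlite::write_json(
    lapply(rules, function(r) list(family = jsonlite::unbox(r$family),
                                   required = r$required,
                                   forbidden = r$forbidden)),
    path)
  invisible(path)
}
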