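# Catalog export, percentage arithmetic and end-to-end pipeline
# orchestration with stage-by-stage waypoint counts.

#' Round half-up
#'
#' Commercial rounding (0.005 -> 0.01), matching printed percentage style,
#' as opposed to R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of TFs in a genome
#'
#' `100 * n_tfs / n_genes`, rounded half-up to 2 decimals.
#'
#' @param n_tfs TF count (>= 0).
#' @param n_genes Protein-coding gene count (>= 1).
#' @return Percentage with 2 decimals.
#' @export
tf_percentage <- function(n_tfs, n_genes) {
  if (any(n_genes < 1)) stop("n_genes must be >= 1")
  if (any(n_tfs < 0)) stop("n_tfs must be >= 0")
  round_half_up(100 * n_tfs / n_genes, 2L)
}

#' Part-of-whole percentage
#'
#' `100 * part / whole`, rounded half-up to 2 decimals.
#'
#' @param part,whole Non-negative counts, `whole >= 1`.
#' @return Percentage with 2 decimals.
#' @export
fraction_report <- function(part, whole) {
  if (any(whole < 1)) stop("whole must be >= 1")
  round_half_up(100 * part / whole, 2L)
}

#' Pipeline configuration
#'
#' @param cluster_threshold_nt,cluster_threshold_aa Identity thresholds of
#'   the nucleotide and protein clustering steps (default 0.95 each).
#' @param word_size_nt,word_size_aa Clustering prefilter word sizes
#'   (8 / 5).
#' @param e_max Domain-hit E-value threshold (default 0.01).
#' @param min_orf_aa Minimum ORF length in residues (default 30).
#' @param genome_gene_count Genome protein-coding gene count used for the
#'   TF-percentage report (default 108569, the wheat gene count).
#' @param rounding Decimal places of reported percentages.
#' @param rng_seed Seed for E-value calibration.
#' @param calib_n_random,calib_len Calibration sample size and protein
#'   length.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(cluster_threshold_nt = 0.95,
                            cluster_threshold_aa = 0.95,
                            word_size_nt = 8L, word_size_aa = 5L,
                            e_max = 0.01, min_orf_aa = 30L,
                            genome_gene_count = 108569L, rounding = 2L,
                            rng_seed = 1L, calib_n_random = 200L,
                            calib_len = 100L) {
  cfg <- as.list(environment())
  stopifnot(cfg$cluster_threshold_nt > 0, cfg$cluster_threshold_nt <= 1,
            cfg$cluster_threshold_aa > 0, cfg$cluster_threshold_aa <= 1,
            cfg$word_size_nt >= 1L, cfg$word_size_aa >= 1L, cfg$e_max > 0,
            cfg$min_orf_aa >= 1L, cfg$genome_gene_count >= 1L)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Export the TF catalog
#'
#' Writes `tf_catalog.tsv` (tf id, family, 7 stage + 7 tissue presence
#' columns, 2 specific flags), `tf_proteins.fasta`, `tf_nucleotides.fasta`
#' and `summary.json`. Summary counts are re-derived from the written TSV
#' and must agree with the in-memory catalog; a mismatch is an error.
#'
#' @param tf_records TF-record data.frame.
#' @param stage_presence,tissue_presence Presence matrices.
#' @param stage_flags,tissue_flags Outputs of [classify_specific()].
#' @param proteins Protein candidates (for `tf_proteins.fasta`).
#' @param ests EST data.frame (for `tf_nucleotides.fasta`).
#' @param out_dir Output directory (created if needed).
#' @param genome_gene_count Denominator of the genome percentage.
#' @return Invisibly, the summary list.
#' @export
export_catalog <- function(tf_records, stage_presence, tissue_presence,
                           stage_flags, tissue_flags, proteins, ests,
                           out_dir, genome_gene_count = 108569L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(tf_records)
  scols <- paste0("stage_", presence_order("stage"))
  tcols <- paste0("tissue_", presence_order("tissue"))
  cat_df <- data.frame(tf_id = tf_records$tf_id, family = tf_records$family,
                       stringsAsFactors = FALSE)
  sp <- if (n) stage_presence[tf_records$tf_id, , drop = FALSE] else
    matrix(integer(), 0, 7)
  tp <- if (n) tissue_presence[tf_records$tf_id, , drop = FALSE] else
    matrix(integer(), 0, 7)
  cat_df[scols] <- as.data.frame(sp)
  cat_df[tcols] <- as.data.frame(tp)
  cat_df$stage_specific <- if (n)
    as.integer(stage_flags$flag[match(tf_records$tf_id, stage_flags$tf_id)] ==
                 "specific") else integer(0)
  cat_df$tissue_specific <- if (n)
    as.integer(tissue_flags$flag[match(tf_records$tf_id, tissue_flags$tf_id)] ==
                 "specific") else integer(0)
  tsv <- file.path(out_dir, "tf_catalog.tsv")
  write.table(cat_df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  if (n) {
    pr <- proteins[match(tf_records$protein_id, proteins$protein_id), ]
    ap <- Biostrings::AAStringSet(pr$protein)
    names(ap) <- tf_records$tf_id
    nt <- ests[match(tf_records$source_est_id, ests$id), ]
    dn <- Biostrings::DNAStringSet(nt$sequence)
    names(dn) <- tf_records$tf_id
  } else {
    ap <- Biostrings::AAStringSet(); dn <- Biostrings::DNAStringSet()
  }
  Biostrings::writeXStringSet(ap, file.path(out_dir, "tf_proteins.fasta"),
                              width = 70L)
  Biostrings::writeXStringSet(dn, file.path(out_dir, "tf_nucleotides.fasta"),
                              width = 70L)

  # re-derive all counts from the written TSV; must agree with memory
  rb <- read.delim(tsv, colClasses = c(rep("character", 2), rep("integer", 16)))
  if (nrow(rb) != n) stop("summary recount mismatch: row count")
  fam_counts <- as.list(table(rb$family))
  stage_specific <- sum(rb$stage_specific)
  tissue_specific <- sum(rb$tissue_specific)
  if (n && stage_specific != sum(stage_flags$flag == "specific"))
    stop("summary recount mismatch: stage-specific count")
  if (n && tissue_specific != sum(tissue_flags$flag == "specific"))
    stop("summary recount mismatch: tissue-specific count")
  per_cat <- function(rb, flags, cols, order) {
    out <- stats::setNames(integer(6), order[1:6])
    if (!nrow(rb)) return(as.list(out))
    spec_rows <- rb[[paste0(sub("_.*", "", cols[1]), "_specific")]] == 1L
    m <- as.matrix(rb[spec_rows, cols[1:6], drop = FALSE])
    out[] <- colSums(m)
    as.list(out)
  }
  summary <- list(
    n_tfs = n,
    family_counts = fam_counts,
    stage_specific_total = stage_specific,
    tissue_specific_total = tissue_specific,
    stage_specific_by_category = per_cat(rb, stage_flags, scols,
                                         presence_order("stage")),
    tissue_specific_by_category = per_cat(rb, tissue_flags, tcols,
                                          presence_order("tissue")),
    pct_stage_specific = if (n) fraction_report(stage_specific, n) else 0,
    pct_tissue_specific = if (n) fraction_report(tissue_specific, n) else 0,
    genome_gene_count = genome_gene_count,
    pct_of_genome = tf_percentage(n, genome_gene_count))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

#' Run the full identification pipeline
#'
#' Corpus -> nucleotide clustering -> six-frame translation -> protein
#' clustering -> profile-HMM scan -> family assignment -> presence ->
#' specificity -> matched-alignment validation -> filtered-sequence
#' recovery -> export, logging waypoint counts at every stage.
#'
#' @param ests,libraries Corpus tables (see [load_corpus()]).
#' @param seeds,rules Family seed alignments and rules.
#' @param config A [pipeline_config()].
#' @param validation_db Optional EST database (`id`, `sequence`,
#'   `library_id`) for matched-alignment validation of putative specific
#'   TFs; `NULL` skips validation.
#' @param out_dir Optional directory for [export_catalog()] output.
#' @return List with `tf_records`, presence matrices and flags (post
#'   validation/recovery), `initial_stage_flags`/`initial_tissue_flags`,
#'   family tables, Venn counts, change logs, clusterings, `report`
#'   (waypoints), and `summary` when exported.
#' @export
run_pipeline <- function(ests, libraries, seeds, rules, config = pipeline_config(),
                         validation_db = NULL, out_dir = NULL) {
  libraries <- categorize_libraries(libraries)
  stage_of <- stats::setNames(libraries$stage_category, libraries$library_id)
  tissue_of <- stats::setNames(libraries$tissue_category, libraries$library_id)
  est_lib <- stats::setNames(ests$library_id, ests$id)

  # 1. nucleotide-level redundancy removal
  nt_seqs <- stats::setNames(ests$sequence, ests$id)
  nt_clusters <- greedy_cluster(nt_seqs, config$cluster_threshold_nt,
                                config$word_size_nt, "nucleotide")
  nt_map <- cluster_map(nt_clusters)
  rep_ids <- vapply(nt_clusters, `[[`, "", "representative_id")
  nonredundant <- ests[ests$id %in% rep_ids, , drop = FALSE]
  filtered <- ests[ests$id %in% names(nt_map), , drop = FALSE]

  # 2. translation
  proteins <- translate_corpus(nonredundant, min_aa = config$min_orf_aa)

  # 3. protein-level redundancy removal
  aa_clusters <- if (nrow(proteins)) {
    greedy_cluster(stats::setNames(proteins$protein, proteins$protein_id),
                   config$cluster_threshold_aa, config$word_size_aa, "protein")
  } else list()
  aa_rep_ids <- vapply(aa_clusters, `[[`, "", "representative_id")
  nr_proteins <- proteins[proteins$protein_id %in% aa_rep_ids, , drop = FALSE]

  # 4. profile build, calibration, scan
  profiles <- lapply(seeds, build_profile)
  profiles <- lapply(seq_along(profiles), function(i) {
    calibrate_evalue(profiles[[i]], config$calib_n_random, config$calib_len,
                     rng_seed = config$rng_seed + i)
  })
  hits <- scan_proteins(nr_proteins, profiles, e_max = config$e_max)

  # 5. family assignment
  candidates <- assign_families(hits, rules)
  assignments <- resolve_multi_family(candidates)
  declared <- vapply(rules, `[[`, "", "family")
  fam_status <- drop_empty_families(assignments, declared)
  tf_records <- mint_tf_ids(assignments, proteins)

  # 6. presence over protein clusters, mapped back to source ESTs
  est_of_protein <- stats::setNames(proteins$source_id, proteins$protein_id)
  est_clusters <- lapply(aa_clusters, function(cl) {
    list(representative_id = unname(est_of_protein[cl$representative_id]),
         member_ids = unname(est_of_protein[cl$member_ids]))
  })
  stage_presence <- build_presence(tf_records, est_clusters, est_lib,
                                   stage_of, "stage")
  tissue_presence <- build_presence(tf_records, est_clusters, est_lib,
                                    tissue_of, "tissue")
  stage_flags0 <- classify_specific(stage_presence)
  tissue_flags0 <- classify_specific(tissue_presence)

  changes <- .empty_changes()

  # 7. matched-alignment validation of putative specific TFs
  if (!is.null(validation_db) && nrow(validation_db) && nrow(tf_records)) {
    for (axis in c("stage", "tissue")) {
      flags <- if (axis == "stage") classify_specific(stage_presence) else
        classify_specific(tissue_presence)
      spec_tfs <- flags$tf_id[flags$flag == "specific"]
      if (!length(spec_tfs)) next
      q <- tf_records[tf_records$tf_id %in% spec_tfs, , drop = FALSE]
      q_ests <- ests[match(q$source_est_id, ests$id), c("id", "sequence")]
      hits_v <- align_against_db(q_ests, validation_db)
      catmap <- if (axis == "stage") stage_of else tissue_of
      upd <- update_from_matches(tf_records,
                                 if (axis == "stage") stage_presence else tissue_presence,
                                 hits_v, catmap, axis)
      if (axis == "stage") stage_presence <- upd$presence else
        tissue_presence <- upd$presence
      changes <- rbind(changes, upd$changes)
    }
  }

  # 8. recovery from filtered-out sequences
  n_filtered_tfs <- 0L
  if (nrow(filtered) && nrow(tf_records)) {
    for (axis in c("stage", "tissue")) {
      catmap <- if (axis == "stage") stage_of else tissue_of
      rec <- recover_filtered(filtered, nt_map, tf_records, profiles,
                              if (axis == "stage") stage_presence else tissue_presence,
                              catmap, axis, min_aa = config$min_orf_aa,
                              e_max = config$e_max)
      if (axis == "stage") stage_presence <- rec$presence else
        tissue_presence <- rec$presence
      changes <- rbind(changes, rec$changes)
      n_filtered_tfs <- rec$n_filtered_tfs
    }
  }

  stage_flags <- classify_specific(stage_presence)
  tissue_flags <- classify_specific(tissue_presence)
  stage_table <- family_category_table(tf_records, stage_flags,
                                       fam_status$retained, axis = "stage")
  tissue_table <- family_category_table(tf_records, tissue_flags,
                                        fam_status$retained, axis = "tissue")
  stage_venn <- venn_region_counts(stage_presence)
  tissue_venn <- venn_region_counts(tissue_presence)

  n_tf <- nrow(tf_records)
  report <- list(
    n_input_ests = nrow(ests),
    n_nonredundant_nt = length(nt_clusters),
    n_filtered_nt = nrow(filtered),
    n_proteins = nrow(proteins),
    n_nonredundant_aa = length(aa_clusters),
    n_scanned_proteins = nrow(nr_proteins),
    n_domain_hits = nrow(hits),
    n_tfs = n_tf,
    n_families_declared = length(declared),
    n_families_retained = length(fam_status$retained),
    n_families_removed = length(fam_status$removed),
    n_filtered_tfs = n_filtered_tfs,
    n_stage_specific_initial = sum(stage_flags0$flag == "specific"),
    n_tissue_specific_initial = sum(tissue_flags0$flag == "specific"),
    n_stage_specific = sum(stage_flags$flag == "specific"),
    n_tissue_specific = sum(tissue_flags$flag == "specific"),
    pct_stage_specific = if (n_tf) fraction_report(
      sum(stage_flags$flag == "specific"), n_tf) else 0,
    pct_tissue_specific = if (n_tf) fraction_report(
      sum(tissue_flags$flag == "specific"), n_tf) else 0,
    # the average-TFs-per-family denominator is ambiguous (declared vs
    # retained families); both are reported
    avg_tfs_per_declared_family = if (length(declared))
      round_half_up(n_tf / length(declared), 2L) else 0,
    avg_tfs_per_retained_family = if (length(fam_status$retained))
      round_half_up(n_tf / length(fam_status$retained), 2L) else 0,
    pct_of_genome = tf_percentage(n_tf, config$genome_gene_count),
    n_changes = nrow(changes))

  out <- list(tf_records = tf_records,
              stage_presence = stage_presence,
              tissue_presence = tissue_presence,
              stage_flags = stage_flags, tissue_flags = tissue_flags,
              initial_stage_flags = stage_flags0,
              initial_tissue_flags = tissue_flags0,
              stage_table = stage_table, tissue_table = tissue_table,
              stage_venn = stage_venn, tissue_venn = tissue_venn,
              changes = changes, nt_clusters = nt_clusters,
              aa_clusters = aa_clusters, proteins = proteins,
              families = fam_status, report = report)
  if (!is.null(out_dir)) {
    out$summary <- export_catalog(tf_records, stage_presence, tissue_presence,
                                  stage_flags, tissue_flags, proteins, ests,
                                  out_dir, config$genome_gene_count)
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
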