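# Synthetic EST corpora with planted ground truth: family membership,
# redundancy structure, stage/tissue specificity, and validation/recovery
# scenarios. The generator emits the exact input formats of the corpus,
# profile-HMM and family-rule modules plus a truth table, so every pipeline
# stage is testable without external databases.

# two fixed synonymous codon tables. Back-translation picks per position
# between them (seeded, so still deterministic); a single fixed table would
# leave the reverse strand of the coding region systematically stop-free,
# letting a reverse-frame ORF outrank the planted one. Swapping every
# choice yields the synonymously diverged variant transcript.
.CODON <- c(A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
            G = "GGC", H = "CAC", I = "ATC", K = "AAG", L = "CTG",
            M = "ATG", N = "AAC", P = "CCA", Q = "CAG", R = "CGT",
            S = "TCC", T = "ACC", V = "GTG", W = "TGG", Y = "TAC")
.ALT_CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
                G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
                M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGC",
                S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

.backtranslate <- function(aa, choice = NULL) {
  v <- strsplit(aa, "")[[1]]
  if (is.null(choice)) choice <- rep(1L, length(v))
  stopifnot(length(choice) == length(v))
  paste(ifelse(choice == 1L, .CODON[v], .ALT_CODON[v]), collapse = "")
}

.random_aa <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                                collapse = "")
.random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Synthetic corpus configuration
#'
#' Defaults describe the standard planted world: 3 families of 8-row seeds
#' over a 40-residue conserved core, 30 TF transcripts, 30 background
#' sequences, 3% domain mutation, 20% same-category duplicates at 97%
#' identity, every TF planted specific, and one blast-update plus one
#' filtered-recovery scenario flipping a planted specific TF to unspecific.
#'
#' @param n_families,seed_sequences_per_family,n_tf_transcripts,n_background
#'   Counts (>= 0; `n_families >= 1`).
#' @param duplicate_rate Fraction of plain TF transcripts that get a
#'   same-library duplicate destined to be clustered away.
#' @param duplicate_identity Nucleotide identity of duplicates, in
#'   \[0.95, 1\].
#' @param n_libraries_per_category Library replicates per (stage, tissue)
#'   pair of the 7 x 7 grid.
#' @param planted_specific_fraction Fraction of TF transcripts planted with
#'   a single informative stage and tissue category; the rest are planted
#'   unspecific (two ESTs from two categories, diverged synonymously so both
#'   survive nucleotide clustering but merge at the protein level).
#' @param mutation_rate_domain Per-position domain mutation rate of each
#'   transcript relative to the family consensus.
#' @param rng_seed Integer seed; the whole corpus is a pure function of the
#'   config.
#' @param core_len Conserved-core length of each family seed (residues).
#' @param n_blast_update,n_filtered_recovery How many planted-specific TFs
#'   get a validation-subject / recoverable-duplicate scenario; `NULL` means
#'   1 each when enough specific TFs exist, else 0.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_families = 3L, seed_sequences_per_family = 8L,
                             n_tf_transcripts = 30L, n_background = 30L,
                             duplicate_rate = 0.2, duplicate_identity = 0.97,
                             n_libraries_per_category = 1L,
                             planted_specific_fraction = 1.0,
                             mutation_rate_domain = 0.03, rng_seed = 1L,
                             core_len = 40L, n_blast_update = NULL,
                             n_filtered_recovery = NULL) {
  cfg <- list(n_families = as.integer(n_families),
              seed_sequences_per_family = as.integer(seed_sequences_per_family),
              n_tf_transcripts = as.integer(n_tf_transcripts),
              n_background = as.integer(n_background),
              duplicate_rate = duplicate_rate,
              duplicate_identity = duplicate_identity,
              n_libraries_per_category = as.integer(n_libraries_per_category),
              planted_specific_fraction = planted_specific_fraction,
              mutation_rate_domain = mutation_rate_domain,
              rng_seed = as.integer(rng_seed),
              core_len = as.integer(core_len),
              n_blast_update = n_blast_update,
              n_filtered_recovery = n_filtered_recovery)
  if (cfg$n_families < 1L) stop("n_families must be >= 1")
  if (cfg$seed_sequences_per_family < 2L)
    stop("seed_sequences_per_family must be >= 2")
  stopifnot(cfg$n_tf_transcripts >= 0L, cfg$n_background >= 0L,
            cfg$n_libraries_per_category >= 1L, cfg$core_len >= 10L)
  if (cfg$duplicate_rate < 0 || cfg$duplicate_rate > 1)
    stop("duplicate_rate must be in [0, 1]")
  if (cfg$duplicate_identity < 0.95 || cfg$duplicate_identity > 1)
    stop("duplicate_identity must be in [0.95, 1]")
  if (cfg$planted_specific_fraction < 0 || cfg$planted_specific_fraction > 1)
    stop("planted_specific_fraction must be in [0, 1]")
  if (cfg$mutation_rate_domain < 0 || cfg$mutation_rate_domain > 1)
    stop("mutation_rate_domain must be in [0, 1]")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate per-family seed alignments and rules
#'
#' Each family gets a gapped alignment of `seed_sequences_per_family`
#' protein rows over a conserved core: at least 60% of core columns are
#' identical across rows, consensus sequences of different families agree at
#' no more than 40% of positions, and one mostly-gap insert column plus
#' sparse row gaps exercise the insert/delete states of profile building.
#' Rules require the family's own domain and forbid all others.
#'
#' @param config A [synthetic_config()].
#' @return List with `seeds` (per family: `family`, `rows`, `consensus`) and
#'   `rules` (family-rule list).
#' @export
generate_family_seeds <- function(config) {
  set.seed(config$rng_seed)
  .generate_seeds_impl(config)
}

.generate_seeds_impl <- function(config) {
  L <- config$core_len
  nfam <- config$n_families
  consensi <- character(0)
  for (f in seq_len(nfam)) {
    ok <- FALSE
    for (try in 1:200) {
      cand <- .random_aa(L)
      ident <- vapply(consensi, function(x) {
        mean(strsplit(cand, "")[[1]] == strsplit(x, "")[[1]])
      }, 0)
      if (any(ident > 0.40)) next
      # viability: some consensi back-translate to sequences whose reverse
      # strand is stop-free under (almost) any synonymous choice, so a
      # reverse-frame ORF would persistently outrank the planted one
      viable <- !inherits(tryCatch(.make_transcript(cand, 30L),
                                   error = function(e) e), "error")
      if (viable) { ok <- TRUE; break }
    }
    if (!ok) stop("core-divergence constraint unsatisfiable for n_families = ",
                  nfam, " at core length ", L)
    consensi <- c(consensi, cand)
  }
  seeds <- vector("list", nfam)
  nrows <- config$seed_sequences_per_family
  for (f in seq_len(nfam)) {
    cons <- strsplit(consensi[f], "")[[1]]
    ok <- FALSE
    for (try in 1:50) {
      conserved <- sort(sample(L, ceiling(0.7 * L)))
      rows <- matrix("", nrows, L)
      for (r in seq_len(nrows)) {
        row <- cons
        varcols <- setdiff(seq_len(L), conserved)
        row[varcols] <- sample(AA_ALPHABET, length(varcols), replace = TRUE)
        # sparse deletions in variable columns (M->D transitions in the seed)
        if (length(varcols) && runif(1) < 0.5)
          row[sample(varcols, 1L)] <- "-"
        rows[r, ] <- row
      }
      # one mostly-gap insert column at an interior position
      ins_at <- sample(2:(L - 1L), 1L)
      ins_col <- rep("-", nrows)
      carriers <- sample(nrows, max(1L, floor(nrows / 4)))
      ins_col[carriers] <- sample(AA_ALPHABET, length(carriers), replace = TRUE)
      rows <- cbind(rows[, 1:ins_at, drop = FALSE], ins_col,
                    rows[, (ins_at + 1L):L, drop = FALSE])
      rows <- unname(apply(rows, 1L, paste, collapse = ""))
      if (.seed_is_detectable(rows, consensi[f], f)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not construct a detectable seed for family ", f,
                  " at core length ", L)
    seeds[[f]] <- list(family = sprintf("FAM%02d", f),
                       rows = rows, consensus = consensi[f])
  }
  fams <- vapply(seeds, `[[`, "", "family")
  rules <- lapply(fams, function(f) {
    list(family = f, required = list(f), forbidden = setdiff(fams, f))
  })
  list(seeds = seeds, rules = rules)
}

# Constructive detectability guarantee: a family seed is accepted only if a
# consensus mutated at 6% (above the <= 5% the planted transcripts use)
# still clears the family's calibrated E-value threshold with margin
# (E < 0.005 in a database of 1000), so every planted TF protein scans below
# e = 0.01 at corpus scale. Randomly drawn seeds can fail this (spiky
# emissions with a fat-tailed null); those are rejected and redrawn.
.seed_is_detectable <- function(rows, consensus, fam_index) {
  cal_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  p <- build_profile(list(family = "check", rows = rows))
  p <- tryCatch(calibrate_evalue(p, 100L, 100L, rng_seed = cal_seed),
                error = function(e) NULL)
  if (is.null(p)) return(FALSE)
  s_req <- p$gumbel_mu + log(1000 / 0.005) / p$gumbel_lambda
  s_min <- min(vapply(1:5, function(i)
    viterbi_score(p, .mutate_aa(consensus, 0.06))$bit_score, 0))
  s_min > s_req
}

.mutate_aa <- function(aa, rate) {
  v <- strsplit(aa, "")[[1]]
  hit <- runif(length(v)) < rate
  v[hit] <- vapply(v[hit], function(ch) sample(setdiff(AA_ALPHABET, ch), 1L), "")
  paste(v, collapse = "")
}

.mutate_nt <- function(dna, n_mut, protect = integer(0)) {
  v <- strsplit(dna, "")[[1]]
  pool <- setdiff(seq_along(v), protect)
  n_mut <- min(n_mut, length(pool))
  pos <- sample(pool, n_mut)
  v[pos] <- vapply(v[pos], function(ch) sample(setdiff(c("A", "C", "G", "T"),
                                                       ch), 1L), "")
  paste(v, collapse = "")
}

# Build one transcript: domain peptide embedded in a coding region flanked
# by UTRs; retries codon choices and UTRs until the planted ORF is the best
# six-frame candidate.
.make_transcript <- function(domain_aa, min_aa) {
  for (try in 1:200) {
    pre_aa <- .random_aa(sample(5:15, 1L))
    post_aa <- .random_aa(sample(5:15, 1L))
    aa <- paste0(pre_aa, domain_aa, post_aa)
    choice <- sample(1:2, nchar(aa), replace = TRUE, prob = c(0.7, 0.3))
    coding <- .backtranslate(aa, choice)
    seqn <- paste0(.random_nt(sample(20:50, 1L)), coding,
                   "TAA", .random_nt(sample(20:50, 1L)))
    bp <- best_protein(seqn, min_aa = min_aa, id = "tmp")
    if (!is.null(bp) && grepl(domain_aa, bp$protein, fixed = TRUE)) {
      dstart <- regexpr(coding, seqn, fixed = TRUE)[1]
      dom_nt_start <- dstart + 3L * nchar(pre_aa) +
        c(0L, 3L * nchar(domain_aa)) - 1L  # 0-based [start, end)
      return(list(sequence = seqn, coding = coding, aa = aa,
                  choice = choice, pre_aa = pre_aa, post_aa = post_aa,
                  domain_nt_range = dom_nt_start))
    }
  }
  stop("could not construct transcript with dominant planted ORF")
}

# Synonymously recode a transcript (protein preserved, every codon choice
# swapped so nucleotide identity drops well below the clustering threshold)
# with fresh UTRs.
.recode_transcript <- function(tr, domain_aa, min_aa) {
  coding2 <- .backtranslate(tr$aa, 3L - tr$choice)
  for (try in 1:50) {
    seqn <- paste0(.random_nt(sample(20:50, 1L)), coding2, "TAA",
                   .random_nt(sample(20:50, 1L)))
    bp <- best_protein(seqn, min_aa = min_aa, id = "tmp")
    if (!is.null(bp) && grepl(domain_aa, bp$protein, fixed = TRUE))
      return(seqn)
  }
  stop("could not construct recoded transcript")
}

#' Generate a synthetic EST corpus with planted truth
#'
#' Emits ESTs, library annotations (a 7 x 7 stage-by-tissue library grid
#' using raw labels the default mappings recognise, including
#' `inflorescence` and `mixed`), family seed alignments and rules, a
#' validation EST database for the blast-update scenario, and a truth table
#' covering every corpus EST exactly once. See [synthetic_config()] for the
#' planted scenarios.
#'
#' @param config A [synthetic_config()].
#' @param min_aa ORF threshold used when verifying constructed transcripts.
#' @return List: `ests`, `libraries`, `seeds`, `rules`, `truth`,
#'   `validation_db` (subject ESTs with libraries), `config`.
#' @export
generate_corpus <- function(config, min_aa = 30L) {
  set.seed(config$rng_seed)
  fam <- .generate_seeds_impl(config)
  seeds <- fam$seeds
  rules <- fam$rules

  stage_inf <- presence_order("stage")[1:6]
  tissue_inf <- presence_order("tissue")[1:6]
  stage_raw <- c(dormant_seed = "dormant seed",
                 germinating_seed = "germinating seed",
                 reproductive = "reproductive", ripening = "ripening",
                 seedling = "seedling", vegetative = "vegetative",
                 unclear = "mixed")
  tissue_raw <- c(crown = "crown", flower = "inflorescence", leaf = "leaf",
                  root = "root", seed = "seed", stem = "stem",
                  other = "callus")
  libs <- expand.grid(stage = names(stage_raw), tissue = names(tissue_raw),
                      rep = seq_len(config$n_libraries_per_category),
                      stringsAsFactors = FALSE)
  libs$library_id <- sprintf("Lib_%s_%s_%d", libs$stage, libs$tissue, libs$rep)
  libraries <- data.frame(library_id = libs$library_id,
                          stage_label = unname(stage_raw[libs$stage]),
                          tissue_label = unname(tissue_raw[libs$tissue]),
                          stringsAsFactors = FALSE)
  lib_for <- function(s, t) {
    cand <- libs$library_id[libs$stage == s & libs$tissue == t]
    if (!length(cand)) stop("no library for category pair ", s, "/", t)
    cand[1L]
  }

  ntf <- config$n_tf_transcripts
  n_spec <- round(config$planted_specific_fraction * ntf)
  n_bu <- config$n_blast_update
  n_fr <- config$n_filtered_recovery
  if (is.null(n_bu)) n_bu <- if (n_spec >= 2L) 1L else 0L
  if (is.null(n_fr)) n_fr <- if (n_spec >= 2L) 1L else 0L
  if (n_bu + n_fr > n_spec)
    stop("scenario counts exceed the number of planted-specific TFs")

  est_rows <- list(); truth_rows <- list()
  val_rows <- list()
  add_est <- function(id, sequence, library_id, family, stage_bits,
                      tissue_bits, dup_of, scenario, domain_aa) {
    est_rows[[length(est_rows) + 1L]] <<- data.frame(
      id = id, sequence = sequence, library_id = library_id,
      stringsAsFactors = FALSE)
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      est_id = id, true_family = family,
      true_stage_presence = stage_bits, true_tissue_presence = tissue_bits,
      is_duplicate_of = dup_of, planted_scenario = scenario,
      domain_peptide = domain_aa, stringsAsFactors = FALSE)
  }
  bits <- function(cats, order) paste(as.integer(order %in% cats),
                                      collapse = "")

  scenario_of <- rep("plain", ntf)
  if (ntf > 0L) {
    spec_idx <- if (n_spec > 0L) seq_len(n_spec) else integer(0)
    if (n_bu > 0L) scenario_of[spec_idx[seq_len(n_bu)]] <- "blast_update"
    if (n_fr > 0L)
      scenario_of[spec_idx[n_bu + seq_len(n_fr)]] <- "filtered_recovery"
    if (n_spec < ntf) scenario_of[(n_spec + 1L):ntf] <- "unspecific"
  }

  for (i in seq_len(ntf)) {
    f <- ((i - 1L) %% config$n_families) + 1L
    fam_name <- seeds[[f]]$family
    domain_aa <- .mutate_aa(seeds[[f]]$consensus, config$mutation_rate_domain)
    tr <- .make_transcript(domain_aa, min_aa)
    s1 <- sample(stage_inf, 1L); t1 <- sample(tissue_inf, 1L)
    s2 <- sample(setdiff(stage_inf, s1), 1L)
    t2 <- sample(setdiff(tissue_inf, t1), 1L)
    id <- sprintf("EST%04d", i)
    sc <- scenario_of[i]

    if (sc == "plain" || sc == "blast_update" || sc == "filtered_recovery") {
      final_s <- if (sc == "plain") s1 else c(s1, s2)
      final_t <- if (sc == "plain") t1 else c(t1, t2)
      add_est(id, tr$sequence, lib_for(s1, t1), fam_name,
              bits(final_s, presence_order("stage")),
              bits(final_t, presence_order("tissue")),
              NA_character_, sc, domain_aa)
      if (sc == "filtered_recovery") {
        dup <- .make_duplicate(tr, config$duplicate_identity)
        add_est(paste0(id, "d"), dup, lib_for(s2, t2), fam_name,
                bits(final_s, presence_order("stage")),
                bits(final_t, presence_order("tissue")),
                id, sc, domain_aa)
      }
      if (sc == "blast_update") {
        val_rows[[length(val_rows) + 1L]] <- data.frame(
          id = paste0(id, "s"),
          sequence = .make_subject(tr),
          library_id = lib_for(s2, t2), query_est = id,
          stringsAsFactors = FALSE)
      }
      if (sc == "plain" && runif(1) < config$duplicate_rate) {
        dup <- .make_duplicate(tr, config$duplicate_identity)
        add_est(paste0(id, "d"), dup, lib_for(s1, t1), fam_name,
                bits(final_s, presence_order("stage")),
                bits(final_t, presence_order("tissue")),
                id, "plain", domain_aa)
      }
    } else {  # planted unspecific: two synonymously diverged ESTs
      sb <- bits(c(s1, s2), presence_order("stage"))
      tb <- bits(c(t1, t2), presence_order("tissue"))
      add_est(id, tr$sequence, lib_for(s1, t1), fam_name, sb, tb,
              NA_character_, "unspecific", domain_aa)
      add_est(paste0(id, "v"), .recode_transcript(tr, domain_aa, min_aa),
              lib_for(s2, t2), fam_name, sb, tb, NA_character_,
              "unspecific", domain_aa)
    }
  }

  for (b in seq_len(config$n_background)) {
    lib <- sample(libs$library_id, 1L)
    add_est(sprintf("BG%04d", b), .random_nt(sample(200:500, 1L)), lib,
            NA_character_, NA_character_, NA_character_, NA_character_,
            "background", NA_character_)
  }

  ests <- if (length(est_rows)) do.call(rbind, est_rows) else
    data.frame(id = character(), sequence = character(),
               library_id = character(), stringsAsFactors = FALSE)
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(est_id = character(), true_family = character(),
               true_stage_presence = character(),
               true_tissue_presence = character(),
               is_duplicate_of = character(), planted_scenario = character(),
               domain_peptide = character(), stringsAsFactors = FALSE)
  vdb <- if (length(val_rows)) do.call(rbind, val_rows) else
    data.frame(id = character(), sequence = character(),
               library_id = character(), query_est = character(),
               stringsAsFactors = FALSE)
  list(ests = ests, libraries = libraries, seeds = seeds, rules = rules,
       truth = truth, validation_db = vdb, config = config)
}

# duplicate: shortened at the 3' end and mutated to ~duplicate_identity,
# never touching the domain's first/last 3 codons. Mutation placement is
# retried until the (mutated) domain still translates stop-free inside the
# duplicate's best ORF, so a filtered-out duplicate remains detectable as a
# TF and its library annotation recoverable.
.make_duplicate <- function(tr, identity) {
  trim <- sample(5:15, 1L)
  seqn <- substr(tr$sequence, 1L, nchar(tr$sequence) - trim)
  protect <- c(seq(tr$domain_nt_range[1] + 1L, tr$domain_nt_range[1] + 9L),
               seq(tr$domain_nt_range[2] - 8L, tr$domain_nt_range[2]))
  n_mut <- round((1 - identity) * nchar(seqn))
  for (try in 1:100) {
    dup <- .mutate_nt(seqn, n_mut, protect = protect)
    dom_nt <- substr(dup, tr$domain_nt_range[1] + 1L, tr$domain_nt_range[2])
    dom_pep <- .translate_frame(dom_nt, 0L)
    if (grepl("*", dom_pep, fixed = TRUE)) next
    bp <- best_protein(dup, min_aa = 30L, id = "dup")
    if (!is.null(bp) && grepl(dom_pep, bp$protein, fixed = TRUE)) return(dup)
  }
  stop("could not construct a scannable duplicate")
}

# blast-update subject: >= 98% identity, strictly longer, ends untouched so
# the local alignment spans the whole query
.make_subject <- function(tr) {
  n <- nchar(tr$sequence)
  protect <- c(1:15, (n - 14L):n)
  mut <- .mutate_nt(tr$sequence, max(1L, round(0.01 * n)), protect = protect)
  paste0(mut, .random_nt(sample(15:30, 1L)))
}

#' Write a synthetic corpus to a directory
#'
#' Materialises the generator output in the pipeline's input formats:
#' `corpus.fasta` + `libraries.tsv` ([load_corpus()] format), one aligned
#' FASTA seed per family, `rules.json`, `truth.tsv`, and the validation
#' database (`validation_db.fasta`, `validation_db_libraries.tsv`).
#'
#' @param corpus Output of [generate_corpus()].
#' @param out_dir Directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_synthetic <- function(corpus, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus(corpus, file.path(out_dir, "corpus.fasta"),
               file.path(out_dir, "libraries.tsv"))
  for (seed in corpus$seeds)
    write_seed_alignment(seed, file.path(out_dir,
                                         paste0(seed$family, ".afa")))
  write_family_rules(corpus$rules, file.path(out_dir, "rules.json"))
  write.table(corpus$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(corpus$validation_db)) {
    x <- Biostrings::DNAStringSet(corpus$validation_db$sequence)
    names(x) <- paste0(corpus$validation_db$id, "|",
                       corpus$validation_db$library_id)
    Biostrings::writeXStringSet(x, file.path(out_dir, "validation_db.fasta"),
                                width = 70L)
  }
  invisible(out_dir)
}
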