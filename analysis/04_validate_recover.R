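#!/usr/bin/env Rscript
# Step 4: matched-alignment validation and filtered-sequence recovery.
#
# The putative specific TFs' source ESTs are aligned against the external
# validation EST database; a hit is a "matched sequence" when coverage of
# the query exceeds 0.95, identity is at least 0.80 and the subject is
# strictly longer. Matched subjects from a different library category add
# that category to the query TF. Separately, every EST removed by the
# nucleotide clustering is translated and re-scanned; filtered-out TFs
# donate their library categories to their cluster representative. Both
# operations only ever set presence bits, so specific counts can only drop.

suppressMessages(library(esttf))

dat <- "results/data"
corpus <- load_corpus(file.path(dat, "corpus.fasta"),
                      file.path(dat, "libraries.tsv"))
seeds <- lapply(list.files(dat, pattern = "\\.afa$", full.names = TRUE),
                read_seed_alignment)
rules <- read_family_rules(file.path(dat, "rules.json"))
vdb <- load_corpus(file.path(dat, "validation_db.fasta"),
                   file.path(dat, "libraries.tsv"))$ests

res <- run_pipeline(corpus$ests, corpus$libraries, seeds, rules,
                    pipeline_config(rng_seed = 1L), validation_db = vdb)

write.table(res$changes, "results/change_log.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

rp <- res$report
message(sprintf("stage-specific: %d putative -> %d after validation/recovery",
                rp$n_stage_specific_initial, rp$n_stage_specific))
message(sprintf("tissue-specific: %d putative -> %d after validation/recovery",
                rp$n_tissue_specific_initial, rp$n_tissue_specific))
message(sprintf("%d filtered-out sequences were themselves TFs; %d presence bits added (%d blast_update, %d filtered_recovery)",
                rp$n_filtered_tfs, nrow(res$changes),
                sum(res$changes$source == "blast_update"),
                sum(res$changes$source == "filtered_recovery")))

# cross-check against the planted truth
truth <- read.delim(file.path(dat, "truth.tsv"), colClasses = "character")
tfr <- res$tf_records
tru <- truth[match(tfr$source_est_id, truth$est_id), ]
planted <- !is.na(tru$true_family) & tru$true_family != "NA" &
  nzchar(tru$true_family)
gs <- apply(res$stage_presence[tfr$tf_id, , drop = FALSE], 1, paste,
            collapse = "")
gt <- apply(res$tissue_presence[tfr$tf_id, , drop = FALSE], 1, paste,
            collapse = "")
message(sprintf("planted-truth agreement: family %.0f%%, stage presence %.0f%%, tissue presence %.0f%%",
                100 * mean(tfr$family[planted] == tru$true_family[planted]),
                100 * mean(gs[planted] == tru$true_stage_presence[planted]),
                100 * mean(gt[planted] == tru$true_tissue_presence[planted])))
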