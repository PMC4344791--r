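#!/usr/bin/env Rscript
# Step 1: simulate the standard EST world.
#
# Emulates the inputs of an EST-based TF survey: a nucleotide EST corpus with
# library annotations (7 developmental-stage x 7 tissue library grid), one
# seed alignment per TF family, the family assignment rules, a validation EST
# database, and the planted truth table. Everything is a pure function of the
# seed (default 1, override with --seed).

suppressMessages(library(esttf))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1L

cfg <- synthetic_config(rng_seed = seed)
corpus <- generate_corpus(cfg)

out <- "results/data"
write_synthetic(corpus, out)
write.table(corpus$validation_db,
            file.path(out, "validation_db_libraries.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

n_dup <- sum(!is.na(corpus$truth$is_duplicate_of))
message(sprintf(
  "simulated %d ESTs (%d TF transcripts incl. %d planted duplicates, %d background)",
  nrow(corpus$ests), sum(grepl("^EST", corpus$ests$id)), n_dup,
  sum(grepl("^BG", corpus$ests$id))))
message(sprintf("scenarios: %d blast_update, %d filtered_recovery",
  sum(corpus$truth$planted_scenario == "blast_update", na.rm = TRUE),
  sum(corpus$truth$planted_scenario == "filtered_recovery" &
        is.na(corpus$truth$is_duplicate_of), na.rm = TRUE)))
message("inputs written under ", out)
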