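#!/usr/bin/env Rscript
# Step 3: stage- and tissue-specificity of the identified TFs.
#
# Builds the two 7-category presence matrices from protein-cluster
# membership and the library annotations, classifies every TF as specific /
# unspecific / unclear on each axis (a TF is specific when exactly one of
# the six informative categories is set; the catch-all column only matters
# when no informative category is), and tabulates family-by-category counts
# and the 127 Venn region counts. Validation and recovery come in step 4;
# the counts here are the initial ("putative") ones.

suppressMessages(library(esttf))

dat <- "results/data"
corpus <- load_corpus(file.path(dat, "corpus.fasta"),
                      file.path(dat, "libraries.tsv"))
seeds <- lapply(list.files(dat, pattern = "\\.afa$", full.names = TRUE),
                read_seed_alignment)
rules <- read_family_rules(file.path(dat, "rules.json"))
res <- run_pipeline(corpus$ests, corpus$libraries, seeds, rules,
                    pipeline_config(rng_seed = 1L))

dir.create("results", showWarnings = FALSE)
wm <- function(m, path) write.table(data.frame(tf_id = rownames(m), m),
                                    path, sep = "\t", quote = FALSE,
                                    row.names = FALSE)
wm(res$stage_presence, "results/stage_presence.tsv")
wm(res$tissue_presence, "results/tissue_presence.tsv")
write.table(merge(res$stage_flags, res$tissue_flags, by = "tf_id",
                  suffixes = c("_stage", "_tissue")),
            "results/specificity_flags.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(family = rownames(res$stage_table$table),
                       res$stage_table$table),
            "results/family_by_stage.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(family = rownames(res$tissue_table$table),
                       res$tissue_table$table),
            "results/family_by_tissue.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
vt <- function(v, path) write.table(
  data.frame(pattern = names(v$regions), count = as.integer(v$regions)),
  path, sep = "\t", quote = FALSE, row.names = FALSE)
vt(res$stage_venn, "results/stage_venn_regions.tsv")
vt(res$tissue_venn, "results/tissue_venn_regions.tsv")

n <- res$report$n_tfs
message(sprintf("%d of %d TFs stage-specific (%.2f%%), %d tissue-specific (%.2f%%) before validation",
                res$report$n_stage_specific, n,
                fraction_report(res$report$n_stage_specific, n),
                res$report$n_tissue_specific,
                fraction_report(res$report$n_tissue_specific, n)))
message(sprintf("Venn regions occupied: %d (stage), %d (tissue)",
                sum(res$stage_venn$regions > 0),
                sum(res$tissue_venn$regions > 0)))
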