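---
title: "Identifying transcription factors and their expression specificity from EST collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying transcription factors and their expression specificity from EST collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esttf)
```

## The model

An EST collection is a sample of expressed transcripts, each tagged with
the cDNA library it came from. Libraries carry free-text annotations of the
developmental stage and tissue they were prepared from; `esttf` folds these
into seven stage categories (dormant seed, germinating seed, seedling,
vegetative, reproductive, ripening, and the catch-all *unclear*) and seven
tissue categories (crown, flower, leaf, root, seed, stem, *other*).
Matching is exact-keyword after case/whitespace normalisation — never
substring, so "germinating seedling trial" does not silently become
"seedling" — and anything unrecognised lands in the catch-all. Users extend
the keyword table through the `overrides` argument of `map_stage()` /
`map_tissue()`; one library maps to exactly one category per axis.

A transcription factor is operationally defined as a protein carrying a
diagnostic DNA-binding domain. The pipeline therefore (i) collapses the
redundant EST set, (ii) translates what remains, (iii) scans the proteins
with one profile hidden Markov model per family, and (iv) applies family
rules to the domain hits. The units the specificity bookkeeping aggregates
over are *clusters*: a TF is present in a category as soon as any EST of
its cluster came from a library of that category.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cluster_threshold_nt` / `cluster_threshold_aa` | 0.95 / 0.95 | identity thresholds (fraction of the shorter sequence) of the two clustering passes |
| `word_size_nt` / `word_size_aa` | 8 / 5 | k-mer prefilter word sizes; advisory only, never change the result |
| `min_orf_aa` | 30 | shortest six-frame ORF kept as a protein candidate (residues) |
| `gap_fraction_max` | 0.5 | seed columns with at least this gap fraction become insert, not match, states |
| `pseudocount` | 1.0 | Laplace smoothing of emission and transition counts |
| `e_max` | 0.01 | domain-hit E-value threshold; `N` = number of scanned proteins |
| `genome_gene_count` | 108569 | denominator of the genome-percentage report (the wheat protein-coding gene count) |

Identity uses the cd-hit convention deliberately: identical aligned
positions of the best local alignment divided by the *shorter* sequence
length, symmetric by construction. The greedy order is length-descending
with input order breaking ties, and a sequence joins the *first* acceptable
cluster, so every clustering is deterministic. The k-mer prefilter is only
consulted when the threshold is at least 0.95 and both sequences are at
least twice the word length, where a shared word is implied by any
above-threshold identity — it can skip work but never change an answer.

## Scoring model

Profiles are "Plan7-lite": per-state match emissions and
match/insert/delete transitions estimated from the seed rows with additive
smoothing, a single shared insert emission equal to the background, no
multi-hit state, one best domain per protein per family. The Viterbi score
is the local path log-odds in bits — emissions as
`log2(P_match/P_background)`, transitions as `log2 P`, entry into and exit
from any match state free, flanking residues emitted by the background at
zero cost. Dynamic programming runs in log space with a finite sentinel
(−10³⁰) for impossible states; residues outside the 20-letter alphabet
(`X` from fuzzy codons) score zero everywhere so they neither help nor
hurt.

E-values come from a method-of-moments Gumbel fit to the scores of
`n_random` (default 200) random proteins: `λ = π/(σ√6)`,
`μ = m − γ/λ`, and `E(S) = N·exp(−λ(S−μ))` clamped to `[0, N]`. The
calibration null is a **fixed uniform residue distribution**, not the
profile's seed-derived background. The null is meant to model the database
being scanned; a seed of a few hundred residues estimates that composition
badly, and using it makes E-values anti-conservative whenever the scanned
proteins do not share the seed's bias — measured on the synthetic world,
off-target planted proteins then passed `e < 0.01` at roughly 5% per
protein–profile pair, which cascades into forbidden-domain collisions. The
fixed null mirrors how production HMM scanners keep their null model
independent of the query profile. The moments fit is crude in the extreme
tail; the self-consistency test checks the 1% exceedance only to binomial
accuracy, and the scanner's residual false-positive rate on background-only
corpora (on the order of `e_max` hits per family) is treated as a measured
property, not assumed to be zero.

## What the generator emulates — and what it does not

`generate_corpus()` builds a corpus in which every downstream answer is
known: families with conserved-core seed alignments (70% conserved columns,
pairwise core identity between families ≤ 40%, one mostly-gap insert column
and sparse row deletions so all profile state types are exercised); TF
transcripts whose domain is the family consensus mutated at 3% per residue,
back-translated and embedded in UTR context with a guaranteed dominant
forward ORF; same-library duplicates at 97% identity destined for the
clustering filter; a 7 × 7 stage-by-tissue library grid using raw labels
the default keyword tables recognise (including `inflorescence` → flower
and `mixed` → unclear); and two planted perturbations — a *blast-update*
subject (≥ 98% identity, strictly longer, different category) in an
external validation database, and a *filtered-recovery* duplicate whose
different category only survives through the recovery step. The truth
table records the **post**-validation/recovery presence vectors.

Three design points deserve their rationale:

* **Back-translation** chooses per position between two fixed synonymous
  codon tables (seeded, hence reproducible). A single fixed table leaves
  the reverse strand of the coding region systematically stop-free, so a
  reverse-frame ORF outranks the planted one; mixing the two tables
  restores reverse-strand stops while keeping the protein unambiguous.
* **Constructive guarantees are enforced, not hoped for.** Seeds are
  redrawn until a 6%-mutated consensus clears the family's calibrated
  detection threshold with margin (`E < 0.005` at `N = 1000`); consensi
  that cannot yield a dominant forward ORF are rejected; duplicate
  mutations are re-placed until the mutated domain still translates
  stop-free inside the duplicate's best ORF. Without these, a randomly
  unlucky seed silently breaks the contract that every planted TF scans
  below `e = 0.01` and every filtered-out duplicate remains recoverable.
* **Background sequences are i.i.d. uniform nucleotides** with no ORF
  control: the scanner's false-positive rate on them is one of the things
  being measured.

A green test on this world therefore establishes that the machinery —
clustering, translation, scoring, rules, bookkeeping, validation, recovery
— is correct, *given* cleanly separated families and honest library labels.
It does not establish robustness to homoeologous subgenome copies,
sequencing error, chimeric ESTs, codon-usage bias, or families that share
domains; real seed alignments and rule tables are user-supplied inputs.

## Numerical choices and degenerate inputs

* Percentages print half-up to two decimals (`round_half_up()`), matching
  the convention of published tables rather than R's banker's rounding.
* Local alignment (validation) scores match +1 / mismatch −2 with affine
  gaps costing `2 + k` for length `k`; the paper-stated matched-sequence
  boundaries are kept exactly: coverage strictly greater than 0.95,
  identity at least 0.80, subject strictly longer.
* `N = N` and `X = X` aligned pairs never count as identical positions.
* Tie-breaks are total and documented: ORF candidates by length, then
  frame order `+1,+2,+3,−1,−2,−3`, then start; multi-family candidates by
  bit score, then smaller rule, then family name; cluster joining by
  founding order.
* Empty corpora, empty FASTA files, all-background corpora and zero
  declared assignments all flow through with empty outputs rather than
  errors; genuinely contradictory configurations (an unsatisfiable family
  count, scenario counts exceeding the specific pool, an all-gap seed)
  fail fast with a message.

## Open design decisions taken

* Presence is aggregated over the **protein-level** clusters, and the
  nucleotide clustering's removed members are what the recovery step
  re-examines. The survey procedure this emulates does not pin down which
  clustering feeds the presence tables; this reading is the one in which
  the recovery step has work to do.
* A TF present in one informative category *and* the catch-all counts as
  specific: the catch-all only decides the classification when every
  informative column is zero.
* "Redundant" sequences in the cross-set report are the non-representative
  cluster members (total minus clusters); the alternative reading (all
  members of non-singleton clusters) is noted in the report header
  semantics but not used.
* Validation is applied only to putative specific TFs, as in the emulated
  survey; `update_from_matches()` accepts any TF set if a caller wants
  otherwise.
* The average-TFs-per-family figure is ambiguous between declared and
  retained families; the run report prints both.

## Known limitations

Pure-R dynamic programming keeps the scanner at desk scale (hundreds of
proteins, profiles of length ≲ 100); the E-value tail is only
moments-accurate; the clustering prefilter is a correctness-preserving
shortcut, not cd-hit's statistical filter; and the shipped family rules
cover only the synthetic families — real 69-family rule tables are an
input, not a deliverable.
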