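#!/usr/bin/env Rscript
# Stage 1 — simulate the study corpus.
#
# Generates the standing desk-scale corpus (10 scaffolds x 100 molecules,
# 2048-bit fingerprints, 20 scaffold-linked labels + 20 background labels,
# pseudo-patent text) and writes the interchange files every later stage
# reads: molecules.csv, truth_labels.csv, patents.jsonl, fingerprints.txt.

suppressMessages(library(chemfunc))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
out_dir <- file.path("results", "corpus")

cfg <- synthetic_config(seed = seed)
corpus <- generate_corpus(cfg)
paths <- write_corpus(corpus, out_dir)

cat(sprintf("corpus: %d molecules over %d scaffolds, %d truth pairs, %d patent documents\n",
            nrow(corpus$molecules), cfg$n_scaffolds, nrow(corpus$truth),
            nrow(corpus$patents)))
cat(sprintf("planted labels: %s ...\n",
            paste(utils::head(corpus$planted_labels, 5), collapse = ", ")))
cat("wrote:", paste(paths, collapse = ", "), "\n")
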