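#!/usr/bin/env Rscript
# Stage 4 — test structural congruence of the functional labels.
#
# For every label: the leave-one-out maximum Tanimoto similarity among its
# molecules, against the same statistic on an equal-sized random set
# (label molecules excluded), Welch two-sided t-test, BH-FDR at 5%. Also
# writes a seeded 2D t-SNE of fingerprint space for label colouring.

suppressMessages(library(chemfunc))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

fingerprints <- read_fingerprints_txt(
  file.path("results", "corpus", "fingerprints.txt"),
  spec = list(type = "synthetic-scaffold-bits", n_bits = 2048L))
dataset <- read_chef_dataset(file.path("results", "chef_dataset.csv"),
                             molecule_ids = rownames(fingerprints$matrix))

res <- run_congruence_analysis(dataset, fingerprints, alpha = 0.05,
                               seed = seed)
cat(sprintf("congruence: %d of %d labels cluster significantly in structure space (5%% FDR)\n",
            attr(res, "n_significant"), nrow(res)))
top <- res[order(res$q_value), ][1:5, c("label", "n", "mean_obs", "mean_null", "q_value")]
cat("strongest labels:\n")
print(top, row.names = FALSE, digits = 3)

utils::write.table(res, file.path("results", "congruence_results.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)

tsne <- project_tsne(fingerprints, perplexity = 50, seed = seed)
utils::write.csv(tsne, file.path("results", "tsne.csv"), row.names = FALSE)
cat("wrote: results/congruence_results.tsv, results/tsne.csv\n")
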