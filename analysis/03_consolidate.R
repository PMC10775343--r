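#!/usr/bin/env Rscript
# Stage 3 — consolidate the label vocabulary.
#
# Embeds the cleaned vocabulary (character n-gram hashing backend), sweeps
# the DBSCAN epsilon under the antiviral/antibacterial/antifungal sentinel
# pairs, summarizes clusters by the abundance-then-lexicographic rule, and
# writes the consolidation map, sweep trace, and the molecule x label
# dataset (chef_dataset.csv + JSON sidecar). Labels on fewer than
# min_molecules molecules are dropped.

suppressMessages(library(chemfunc))

min_molecules <- 50L
cleaned <- utils::read.csv(file.path("results", "cleaned_labels.csv"),
                           colClasses = "character")
molecules <- read_molecules_csv(file.path("results", "corpus", "molecules.csv"))

# Sentinels operationalize "cluster quality deterioration": the classic
# antiviral/antibacterial/antifungal trio plus morphological traps an
# orthographic (n-gram) embedding is prone to merging.
sentinels <- list(
  c("antiviral", "antibacterial"), c("antiviral", "antifungal"),
  c("antibacterial", "antifungal"), c("agonist", "antagonist"),
  c("herbicide", "fungicide")
)
cons <- consolidate_vocabulary(
  cleaned, ngram_embedding_backend(256),
  eps_grid = seq(0.05, 0.6, by = 0.05),
  sentinel_pairs = sentinels,
  min_molecules = min_molecules,
  molecule_ids = molecules$molecule_id
)
cat(sprintf("epsilon sweep: chose eps = %.2f (%d labels -> %d clusters, sentinels %s)\n",
            cons$model$epsilon, length(cons$model$assignments),
            cons$model$n_clusters,
            if (cons$model$sentinel_ok) "separated" else "VIOLATED"))
cat(sprintf("dataset: %d molecules x %d labels after the <%d-molecule filter (%d before)\n",
            length(cons$dataset$molecule_ids), length(cons$dataset$labels),
            min_molecules, length(cons$unfiltered$labels)))

utils::write.csv(cons$map, file.path("results", "consolidation_map.csv"),
                 row.names = FALSE)
utils::write.csv(cons$model$trace, file.path("results", "sweep_trace.csv"),
                 row.names = FALSE)
write_chef_dataset(cons$dataset, "results",
                   meta = list(embedding_backend = "ngram-hash",
                               epsilon = cons$model$epsilon,
                               min_molecules = min_molecules))
cat("wrote: results/consolidation_map.csv, results/sweep_trace.csv, results/chef_dataset.csv\n")
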