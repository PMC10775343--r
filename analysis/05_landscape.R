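#!/usr/bin/env Rscript
# Stage 5 — build the text-based functional landscape.
#
# Counts per-molecule label co-occurrence into a weighted label graph,
# detects modularity communities at resolution 0.5, and tests per label
# whether the molecules of its top-10 co-occurring labels (< 1,000
# abundance) are closer in structure space than an equal-sized random set.
# Exports Gephi-ready GraphML/GEXF plus the coherence and community tables.

suppressMessages(library(chemfunc))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

fingerprints <- read_fingerprints_txt(
  file.path("results", "corpus", "fingerprints.txt"),
  spec = list(type = "synthetic-scaffold-bits", n_bits = 2048L))
dataset <- read_chef_dataset(file.path("results", "chef_dataset.csv"),
                             molecule_ids = rownames(fingerprints$matrix))

land <- run_landscape_analysis(dataset, fingerprints, alpha = 0.05,
                               k = 10, abundance_cap = 1000,
                               resolution = 0.5, seed = seed)
cat(sprintf("landscape: %d nodes, %d edges, %d communities (modularity %.3f)\n",
            igraph::vcount(land$graph), igraph::ecount(land$graph),
            land$partition$n_communities, land$partition$modularity))
cat(sprintf("coherence: %d of %d testable labels align with their text neighbourhood (5%% FDR); %d skipped\n",
            attr(land$results, "n_significant"), nrow(land$results),
            nrow(land$skipped)))

utils::write.table(land$results, file.path("results", "coherence_results.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
utils::write.csv(
  data.frame(label = names(land$partition$membership),
             community = unname(land$partition$membership)),
  file.path("results", "communities.csv"), row.names = FALSE)
write_landscape_graphml(land$graph, land$partition,
                        file.path("results", "landscape.graphml"))
write_landscape_gexf(land$graph, land$partition,
                     file.path("results", "landscape.gexf"))
cat("wrote: results/coherence_results.tsv, results/communities.csv, results/landscape.{graphml,gexf}\n")
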