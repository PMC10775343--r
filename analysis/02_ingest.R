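#!/usr/bin/env Rscript
# Stage 2 — ingest the corpus and extract functional labels.
#
# Reads molecules.csv + patents.jsonl written by stage 1, applies the
# patent-count filter (< 10 patents), runs the dictionary extraction
# backend over the truncated patent text (title + abstract + first 3,500
# description characters), cleans the raw labels (lowercase, word split,
# singularize), and writes raw_labels.csv and cleaned_labels.csv.

suppressMessages(library(chemfunc))

corpus_dir <- file.path("results", "corpus")
molecules <- read_molecules_csv(file.path(corpus_dir, "molecules.csv"))
patents <- read_patents_jsonl(file.path(corpus_dir, "patents.jsonl"))
truth <- utils::read.csv(file.path(corpus_dir, "truth_labels.csv"),
                         colClasses = "character")

kept <- filter_by_patent_count(molecules, max_exclusive = 10)
cat(sprintf("patent-count filter: %d kept, %d dropped\n",
            attr(kept, "n_kept"), attr(kept, "n_dropped")))
patents <- patents[patents$molecule_id %in% kept$molecule_id, ]

backend <- mock_extraction_backend(unique(truth$label))
raw <- extract_labels(backend, patents)
cat(sprintf("extraction: %d raw label rows from %d documents (%d failures)\n",
            nrow(raw), nrow(patents), length(attr(raw, "failures"))))

cleaned <- clean_labels(raw)
cat(sprintf("cleaning: %d molecule-label pairs over %d unique labels\n",
            nrow(cleaned), length(unique(cleaned$label))))

utils::write.csv(raw, file.path("results", "raw_labels.csv"), row.names = FALSE)
utils::write.csv(cleaned, file.path("results", "cleaned_labels.csv"),
                 row.names = FALSE)
cat("wrote: results/raw_labels.csv, results/cleaned_labels.csv\n")
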