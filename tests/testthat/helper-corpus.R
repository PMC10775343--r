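# Shared fixture builders. Everything is generated in code at test time;
# corpora are cached per (config hash) within a session to keep the suite fast.

.corpus_cache <- new.env(parent = emptyenv())

cached_corpus <- function(key, config, ...) {
  if (!exists(key, envir = .corpus_cache)) {
    assign(key, generate_corpus(config, ...), envir = .corpus_cache)
  }
  get(key, envir = .corpus_cache)
}

# The standing desk-scale study corpus (generator defaults, fixed seed).
study_corpus <- function() {
  cached_corpus("study", synthetic_config(seed = 101), with_patents = FALSE)
}

# Small zero-noise corpus with patent text, for ingest round trips.
roundtrip_corpus <- function() {
  cached_corpus(
    "roundtrip",
    synthetic_config(n_scaffolds = 5, members_per_scaffold = 10, n_bits = 256,
                     n_planted_labels = 10, labels_per_scaffold = 2,
                     n_background_labels = 0, background_rate = 0,
                     label_noise = 0, patents_per_molecule = 2, seed = 11)
  )
}

# Tiny SMILES-track corpus exercising the chemistry code path.
smiles_corpus <- function() {
  cached_corpus(
    "smiles",
    synthetic_config(n_scaffolds = 6, members_per_scaffold = 10,
                     n_planted_labels = 6, labels_per_scaffold = 1,
                     n_background_labels = 0, background_rate = 0,
                     label_noise = 0, patents_per_molecule = 1, seed = 13),
    track = "smiles"
  )
}

truth_dataset <- function(corpus) {
  chef_dataset(corpus$truth, molecule_ids = corpus$molecules$molecule_id)
}

# Independent quadratic oracle for the leave-one-out max statistic.
loo_max_bruteforce <- function(m) {
  n <- nrow(m)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- -Inf
    for (j in seq_len(n)) {
      if (i == j) next
      inter <- sum(m[i, ] & m[j, ])
      uni <- sum(m[i, ] | m[j, ])
      s <- if (uni == 0) 0 else inter / uni
      if (s > best) best <- s
    }
    out[i] <- best
  }
  out
}

# Textbook Benjamini-Hochberg step-up, written independently of p.adjust:
# sort ascending, scale by m/rank, take the cumulative minimum from the tail.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(scaled)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}
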