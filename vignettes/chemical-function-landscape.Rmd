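---
title: "Methods: text-derived chemical function landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: text-derived chemical function landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`chemfunc` implements a pipeline that turns patent text into a
molecule-by-function dataset and then asks, statistically, whether the
text-derived functional vocabulary is congruent with chemical structure
space. The pipeline has five stages, each an exported module surface:

1. **Corpus ingestion** — SMILES canonicalization, patent-count filtering,
   text truncation, backend-driven label extraction, label cleaning.
2. **Vocabulary consolidation** — label embedding, density clustering with
   an epsilon sweep, cluster summarization, abundance filtering.
3. **Structural congruence** — per-label maximum-Tanimoto statistics
   against resampled nulls with Welch t-tests and BH-FDR control.
4. **Co-occurrence landscape** — a weighted label co-occurrence graph,
   modularity communities, and coherence tests of each label's text
   neighbourhood in structure space.
5. **Structure-to-function classification** — one-vs-rest logistic /
   random-forest models and a multi-output feedforward network on binary
   fingerprints, with ranked retrieval and profile annotation.

A synthetic corpus generator provides the whole pipeline with a
self-contained test surface: no chemistry downloads, no external APIs.

# The congruence statistic

For a label $\ell$ carried by molecules $M_\ell$, the observed sample is
the leave-one-out maximum Tanimoto similarity

$$ s_i = \max_{j \in M_\ell,\, j \neq i} \frac{|f_i \wedge f_j|}{|f_i \vee f_j|}, \qquad i \in M_\ell $$

over binary fingerprints $f$. Self-comparison is excluded; otherwise the
statistic is identically 1. The null sample applies the same statistic to
a uniformly drawn molecule set of size $|M_\ell|$, sampled without
replacement from the molecules *not* carrying the label (exclusion
sharpens the null; when the dataset is smaller than twice the label the
draw falls back to the full population and the result is flagged
degenerate). The two samples are compared with a two-sided Welch t-test
and the per-label p-values receive Benjamini–Hochberg correction across
the whole family; a label is "significantly clustered" when its q-value
is below $\alpha = 0.05$.

The coherence test of stage 4 replaces the within-set maximum by the
maximum similarity from each label molecule to the union of molecules of
the label's ten most frequently co-occurring labels, subject to a strict
abundance cap (default 1,000 molecules): hyper-abundant neighbours would
blanket structure space and force every maximum to 1. The null draws a
random molecule set of the target's size. Only the query molecule itself
is excluded from the target — molecules legitimately carry both the label
and its neighbours.

## Known statistical limitations

Two properties of this procedure deserve emphasis, because they shape what
the tests can and cannot show.

*Within-set dependence.* The $s_i$ are not independent: one unusually
central molecule (a low-noise "hub") can be the maximizing partner of many
set members at once. The t-test assumes independence, so raw p-values are
anti-conservative under the null — on a structureless population the
fraction of raw $p < 0.05$ runs well above 5% — while the BH-flagged
fraction at 5% FDR stays controlled in our simulations. Census counts
should therefore be read from the FDR-corrected column only.

*Power under compact populations.* The gap between the observed and null
means is the difference between the expected maximum over $|M_\ell|-1$
within-family similarities and the expected maximum over the same-family
similarities a random set happens to contain. In a population composed of
a few large structural families, a random set of label size contains many
same-family pairs, the gap shrinks to a fraction of the similarity
spread, and label-reassignment noise (strays with near-zero similarity)
inflates the observed-sample variance. Both effects reduce the power of
the t-test substantially. The default desk-scale corpus (10 scaffolds of
100 molecules) sits in exactly this compact regime, and its planted-label
detection rate is far below what the same statistic achieves on a diverse
population in which random sets are structurally diffuse — the regime
real patent corpora occupy. The package reports what the statistic
honestly yields under the stated conditions rather than restructuring the
population to flatter it.

# The synthetic corpus

`synthetic_config()` defines the study conditions; `generate_corpus()`
materialises them. The generator emulates:

- **Scaffold structure.** Each scaffold has a prototype bit vector with
  exactly `round(prototype_density * n_bits)` set bits (positions random
  per scaffold). Members flip every prototype bit independently with
  probability `flip_rate`. Equal prototype weights keep scaffolds
  structurally exchangeable, so differences between labels reflect
  membership, not nuisance variation in scaffold complexity.
- **Label structure.** Planted labels attach to all molecules of their
  scaffold (two labels per scaffold by default, giving every label one
  strongly co-occurring partner), then each attachment is reassigned to a
  random molecule with probability `label_noise`. Background labels
  attach independently per molecule — a calibrated negative class with no
  structural signal.
- **Patent text.** Each molecule gets `patents_per_molecule` documents
  whose abstract and description interleave filler prose with sentences
  containing every truth-label keyword. Keyword order rotates across a
  molecule's documents so a backend limited to three labels per document
  recovers the full set across documents; descriptions are padded past
  3,500 characters with all keywords before that offset, so truncation is
  genuinely exercised.

Defaults (the standing desk-scale conditions): 10 scaffolds × 100
members, 2,048 bits, prototype density 0.05, flip rate 0.02, 20 planted +
20 background labels, background rate 0.05, label noise 0.02, 3 patents
per molecule. The 2% label noise mirrors the realistic share of
patent-derived labels that do not describe their own molecule (validation
studies of LLM extraction put label relevance near 98%). The classifier
stress tests raise the noise to 5% to show recovery is not an artifact of
clean labels.

What the generator does **not** emulate: realistic medicinal-chemistry
scaffolds, patent legalese, hierarchical scaffold families, correlated
background labels, or the long-tailed abundance distribution of real
vocabularies. Passing tests show the machinery is correct and calibrated
under the planted model; they do not certify performance on real corpora.

A second track (`generate_corpus(..., track = "smiles")`) decorates a
built-in library of template SMILES with random substituents, so the
chemistry code path — OpenBabel canonicalization and fingerprinting —
is exercised on genuine molecules.

# Stage-by-stage choices

**Canonicalization** uses OpenBabel canonical SMILES (via ChemmineOB):
valid strings are canonicalized preserving stereochemistry, malformed
strings dropped and counted, duplicate canonical forms merged with the
union of their patent ids (merging preserves information; dropping would
not). Conversion runs per molecule because the batch converter stops at
the first malformed entry.

**Patent-count filter**: strictly fewer than 10 patents. Over-patented
molecules accumulate patents irrelevant to their function and would
dilute the labels.

**Extraction** routes through a backend interface. The shipped backend is
deterministic dictionary keyword spotting over the truncated text
(title + abstract + first 3,500 description characters), returning
matches in first-occurrence order; output beyond three labels per
document is clipped with a warning, and empty output becomes a recorded
per-document failure. A live LLM adapter can implement the same
interface; none ships enabled.

**Cleaning** lowercases, splits on whitespace, strips edge punctuation
(internal hyphens survive, so "5-ht" is stable), and singularizes by
rule: final "s" dropped unless the token ends in "ss"/"us"/"is" or sits
on a protected irregular list ("diabetes", "species", ...). The rule is
deliberately simple, deterministic, and idempotent.

**Consolidation** embeds the vocabulary (any `embedding_backend`; the
shipped default hashes character trigrams into 256 buckets and
L2-normalizes), then sweeps DBSCAN's epsilon over an ascending grid with
cosine distance and `min_samples = 2` (a cluster is any mutually close
pair). The chosen epsilon is the largest under which no *sentinel pair*
shares a cluster — the operational form of "minimum clusters without
quality deterioration", with antiviral/antibacterial/antifungal as the
default sentinels. Noise points become singleton clusters mapping to
themselves, so rare specific labels survive. Cluster summarization picks
the most abundant member (ties lexicographic); an LLM summarizer can be
plugged in but the frequency rule keeps runs deterministic. An epsilon
of 0.34 is only meaningful for a specific embedding geometry; the sweep
is the portable procedure. The orthographic trigram backend is prone to
merging morphological neighbours with opposite meanings
(agonist/antagonist), which is exactly what extra sentinel pairs are
for — the stage-3 analysis script demonstrates this.

**Fingerprints** for real molecules are OpenBabel FP2 path-based
substructure fingerprints (1,024 bits), the substructure fingerprint the
available toolkit provides; the spec of whichever fingerprint was used is
recorded in the result object and checked at prediction time. The
synthetic bit track uses 2,048-bit scaffold fingerprints directly.

**Communities** come from igraph's Louvain implementation at resolution
0.5, seeded. Community counts are heuristic and seed-dependent; they are
reported as descriptive statistics, not tested quantities. On the small
dense synthetic graph, resolution 0.5 under-resolves (often one or two
communities); resolution 1 recovers the scaffold pairing. The default
stays at 0.5 — the value appropriate for the sparse, large vocabularies
the method targets.

**Classifier families**: one-vs-rest ridge logistic regression (glmnet,
`lambda = 1/(n C)` with C = 0.001, max 1,000 iterations), random forest
(ranger, 100 trees, depth ≤ 10, per-label seeds), and a multi-output
feedforward network (512, 256 hidden units, ReLU, dropout 0.2, minibatch
32, Adam at 0.001, 5 epochs, binary cross-entropy with logits) written in
plain R matrix operations. Labels lacking both classes in the training
split are masked — skipped, recorded, excluded from macro averages —
rather than failing the run. All model outputs are probabilities
(forest: positive-class vote fraction). "Positive predictive power" is
operationalized as test ROC-AUC > 0.5. ROC-AUC uses the rank
(Mann–Whitney) formula with average ranks for ties, so a constant scorer
gets exactly 0.5; PR-AUC is step-interpolated average precision with tied
scores handled as single threshold blocks. Cross-validated re-tuning of
the network hyperparameters is out of scope; the stated values are the
defaults.

**t-SNE** projections call scikit-learn through the system `python` with
an explicit `random_state`; perplexity must be below the molecule count
(500 suits ~100K-molecule corpora; small sets need small perplexities).

# Numerical and degenerate-input conventions

- Tanimoto similarity of two all-zero vectors is 0 by convention.
- Welch tests on zero-variance samples: equal constants give $t = 0$,
  $p = 1$; different constants give $t = \pm\infty$, $p = 0$.
- The leave-one-out statistic requires at least two molecules; labels
  below that are excluded from the congruence family, and coherence
  skips (with recorded reasons) labels lacking eligible neighbours.
- Significance is strict: $q < \alpha$.
- Retrieval ties break by molecule id; summarization ties break
  lexicographically; both keep runs reproducible.
- All randomness flows through explicit seeds; run-level seeds derive
  per-label child seeds so results are invariant to label order.

# Problem sizes

The package's own analyses and tests run at desk scale: 1,000-molecule
corpora (10 × 100), 2,048-bit fingerprints, 40-label vocabularies, 200
random labels for type-I calibration, and a 10% hold-out for the
classifiers. These sizes make the full pipeline — generation, ingestion,
consolidation, both statistical censuses, and classifier training — run
in well under a minute each while keeping Monte-Carlo margins tight
enough for the calibration checks. The same code paths scale to the
100K-molecule regime the method targets; only the t-SNE perplexity and
the rare-label threshold need rethinking at other scales.
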