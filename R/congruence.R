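#' Compute binary substructure fingerprints from SMILES
#'
#' Converts canonical SMILES to binary substructure fingerprints through the
#' OpenBabel toolkit (ChemmineR/ChemmineOB). The default `"FP2"` is a
#' 1024-bit path-based substructure fingerprint; `"ap"` hashes ChemmineR
#' atom-pair descriptors into 1024 bits. The fingerprint spec is recorded in
#' the result and propagated into every downstream artifact for provenance.
#'
#' @param records data.frame with `molecule_id` and `smiles` columns, or a
#'   named character vector of SMILES.
#' @param type fingerprint type: `"FP2"` (default) or `"ap"`.
#' @return a [fingerprint_matrix()].
#' @export
compute_fingerprints <- function(records, type = c("FP2", "ap")) {
  type <- match.arg(type)
  if (is.character(records)) {
    ids <- names(records) %||% sprintf("mol%05d", seq_along(records))
    records <- data.frame(molecule_id = ids, smiles = unname(records),
                          stringsAsFactors = FALSE)
  }
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("ChemmineR and ChemmineOB are required to fingerprint SMILES", call. = FALSE)
  }
  smiles <- stats::setNames(records$smiles, records$molecule_id)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  failed <- !ChemmineR::validSDF(sdf)
  if (any(failed) || length(sdf) != length(smiles)) {
    stop(sprintf("unparseable SMILES reached fingerprinting (e.g. %s); canonicalize first",
                 paste(utils::head(records$molecule_id[failed], 3L), collapse = ", ")),
         call. = FALSE)
  }
  if (type == "FP2") {
    fp <- ChemmineR::fingerprintOB(sdf, "FP2")
  } else {
    fp <- ChemmineR::desc2fp(ChemmineR::sdf2ap(sdf), descnames = 1024,
                             type = "FPset")
  }
  mat <- fp@fpma  # FPset slot; avoids relying on attached S4 methods
  rownames(mat) <- records$molecule_id
  fingerprint_matrix(mat, spec = list(
    type = paste0("openbabel-", type), n_bits = ncol(mat), toolkit = "ChemmineOB"
  ))
}

#' Tanimoto similarity of two binary vectors
#'
#' `|a AND b| / |a OR b|`; two all-zero vectors have similarity 0 by
#' convention.
#'
#' @param a,b binary vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprint length mismatch", call. = FALSE)
  }
  a <- as.logical(a)
  b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

# Pairwise Tanimoto similarities between the rows of two 0/1 matrices.
# Intersections via a single matrix product; all-zero pairs get 0.
tanimoto_cross <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  inter <- tcrossprod(a, b)
  ra <- rowSums(a)
  rb <- rowSums(b)
  uni <- outer(ra, rb, "+") - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  dimnames(sim) <- list(rownames(a), rownames(b))
  sim
}

#' Leave-one-out maximum Tanimoto similarity within a molecule set
#'
#' For each molecule in the set, the maximum Tanimoto similarity to any
#' *other* molecule of the set. Self-comparison is excluded, otherwise the
#' statistic is identically 1.
#'
#' @param fp a [fingerprint_matrix()] or binary matrix of the set's rows.
#' @return numeric vector of per-molecule maxima (named by molecule id).
#' @export
leave_one_out_max <- function(fp) {
  m <- if (inherits(fp, "fingerprint_matrix")) fp$matrix else as.matrix(fp)
  if (nrow(m) < 2L) {
    stop("leave-one-out maximum requires at least 2 molecules", call. = FALSE)
  }
  sim <- tanimoto_cross(m, m)
  diag(sim) <- -Inf
  apply(sim, 1L, max)
}

# Per-row maximum similarity from set A to set B, excluding any B column
# whose molecule id equals the query row's id.
max_sim_to_set <- function(fp_a, fp_b) {
  a <- if (inherits(fp_a, "fingerprint_matrix")) fp_a$matrix else as.matrix(fp_a)
  b <- if (inherits(fp_b, "fingerprint_matrix")) fp_b$matrix else as.matrix(fp_b)
  sim <- tanimoto_cross(a, b)
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    shared <- intersect(rownames(a), rownames(b))
    for (id in shared) sim[id, id] <- -Inf
  }
  out <- apply(sim, 1L, max)
  out[is.infinite(out)] <- NA_real_
  out
}

# Welch two-sided t-test robust to zero-variance degenerate samples
# (identical constant samples -> t = 0, p = 1; different constants ->
# t = +/-Inf, p = 0).
welch_test <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    d <- mean(x) - mean(y)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                p = if (d == 0) 1 else 0))
  }
  ht <- stats::t.test(x, y, alternative = "two.sided", var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Structural-clustering test for one label
#'
#' Observed statistic: leave-one-out maximum Tanimoto similarity over the
#' molecules carrying the label. Null: the same statistic over a uniformly
#' sampled set of equal size, drawn without replacement from the molecules
#' *not* carrying the label (sharpening the null); when the dataset is too
#' small to exclude them the draw falls back to the full population and the
#' result is flagged degenerate. Several null replicates can be pooled.
#' Significance is a two-sided Welch t-test between observed and null
#' samples; family-wide FDR is applied later by the runner.
#'
#' @param label a label with abundance >= 2.
#' @param dataset a `chef_dataset`.
#' @param fingerprints a [fingerprint_matrix()] covering the dataset's
#'   molecules.
#' @param n_null_reps number of pooled null replicates (default 1).
#' @param seed RNG seed for the null draw.
#' @return one-row data.frame: label, n, mean_obs, mean_null, t_stat,
#'   p_value, degenerate.
#' @export
label_clustering_test <- function(label, dataset, fingerprints,
                                  n_null_reps = 1L, seed = 1L) {
  stopifnot(inherits(dataset, "chef_dataset"))
  mols <- label_molecules(dataset, label)
  n <- length(mols)
  if (n < 2L) {
    stop(sprintf("label '%s' has abundance %d; the statistic needs >= 2", label, n),
         call. = FALSE)
  }
  pool <- setdiff(dataset$molecule_ids, mols)
  degenerate <- length(pool) < n
  if (degenerate) pool <- dataset$molecule_ids
  observed <- leave_one_out_max(fingerprints[mols])
  null_vals <- with_seed(seed, {
    unlist(lapply(seq_len(n_null_reps), function(r) {
      leave_one_out_max(fingerprints[sample(pool, n)])
    }))
  })
  ht <- welch_test(observed, null_vals)
  data.frame(
    label = label, n = n,
    mean_obs = mean(observed), mean_null = mean(null_vals),
    t_stat = ht$t, p_value = ht$p, degenerate = degenerate,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up q-values with monotonicity enforcement; a label is flagged
#' significant when its q-value is below `alpha`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list with `q_values` and logical `flags`.
#' @export
fdr_correct <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) {
    return(list(q_values = numeric(0), flags = logical(0)))
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, flags = !is.na(q) & q < alpha)
}

#' Per-label structural-congruence census
#'
#' Runs [label_clustering_test()] for every label with abundance >= 2,
#' applies BH-FDR across the whole family, and reports the number of labels
#' significantly clustered in structure space.
#'
#' @param dataset a filtered `chef_dataset`.
#' @param fingerprints a [fingerprint_matrix()].
#' @param alpha FDR level.
#' @param n_null_reps pooled null replicates per label.
#' @param seed run seed; each label receives a derived child seed.
#' @param labels optional label subset (default: all testable labels).
#' @return data.frame of `CongruenceResult` rows (label, n, mean_obs,
#'   mean_null, t_stat, p_value, q_value, significant, degenerate) with
#'   attribute `n_significant`.
#' @export
run_congruence_analysis <- function(dataset, fingerprints, alpha = 0.05,
                                    n_null_reps = 1L, seed = 1L,
                                    labels = NULL) {
  stopifnot(inherits(dataset, "chef_dataset"))
  labels <- labels %||% dataset$labels
  labels <- labels[dataset$abundance[labels] >= 2]
  rows <- lapply(seq_along(labels), function(i) {
    label_clustering_test(labels[i], dataset, fingerprints,
                          n_null_reps = n_null_reps,
                          seed = child_seed(seed, i))
  })
  out <- do.call(rbind, rows) %||% data.frame(
    label = character(0), n = integer(0), mean_obs = numeric(0),
    mean_null = numeric(0), t_stat = numeric(0), p_value = numeric(0),
    degenerate = logical(0)
  )
  fdr <- fdr_correct(out$p_value, alpha)
  out$q_value <- fdr$q_values
  out$significant <- fdr$flags
  rownames(out) <- NULL
  attr(out, "n_significant") <- sum(out$significant)
  attr(out, "alpha") <- alpha
  out
}

#' Two-dimensional t-SNE projection of fingerprint space
#'
#' Projects the binary fingerprint matrix to 2D with scikit-learn's t-SNE
#' (run through the system `python`), seeded for reproducibility. The
#' perplexity must be smaller than the number of molecules.
#'
#' @param fingerprints a [fingerprint_matrix()].
#' @param perplexity t-SNE perplexity (default 500, suitable for
#'   100K-molecule corpora; use much smaller values on small sets).
#' @param seed random state passed to t-SNE.
#' @param python path to the python interpreter.
#' @return data.frame (`molecule_id`, `x`, `y`) with attribute `perplexity`.
#' @export
project_tsne <- function(fingerprints, perplexity = 500, seed = 0L,
                         python = Sys.which("python")) {
  m <- fingerprints$matrix
  if (perplexity >= nrow(m)) {
    stop(sprintf("perplexity (%g) must be < number of molecules (%d)",
                 perplexity, nrow(m)), call. = FALSE)
  }
  if (!nzchar(python)) stop("no python interpreter found for t-SNE", call. = FALSE)
  fin <- tempfile(fileext = ".txt")
  fout <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.table(m, fin, row.names = FALSE, col.names = FALSE)
  code <- paste(
    "import sys, numpy as np",
    "from sklearn.manifold import TSNE",
    "X = np.loadtxt(sys.argv[1])",
    sprintf("emb = TSNE(n_components=2, perplexity=%g, random_state=%d, init='pca').fit_transform(X)",
            perplexity, as.integer(seed)),
    "np.savetxt(sys.argv[2], emb)",
    sep = "; "
  )
  status <- system2(python, c("-c", shQuote(code), shQuote(fin), shQuote(fout)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(fout)) {
    stop("t-SNE projection failed (python/scikit-learn error)", call. = FALSE)
  }
  emb <- as.matrix(utils::read.table(fout))
  out <- data.frame(molecule_id = rownames(m), x = emb[, 1], y = emb[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "perplexity") <- perplexity
  out
}
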