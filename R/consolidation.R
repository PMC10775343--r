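#' Construct a label-embedding backend
#'
#' A backend maps label strings to fixed-length numeric vectors; the sweep
#' clusters those vectors to consolidate grammatically dissimilar but
#' semantically similar labels. Any function with the right signature can be
#' wrapped, including an adapter for a hosted embedding API.
#'
#' @param name backend name (recorded in outputs).
#' @param embed function(labels) -> numeric matrix, one row per label.
#' @return an `embedding_backend`.
#' @export
embedding_backend <- function(name, embed) {
  stopifnot(is.character(name), is.function(embed))
  structure(list(name = name, embed = embed), class = "embedding_backend")
}

#' Identity embedding backend
#'
#' Assigns every distinct label its own orthogonal unit vector, so all
#' pairwise cosine distances equal 1 and density clustering at any epsilon
#' below 1 leaves the vocabulary untouched. Useful as the neutral backend in
#' round-trip runs where no consolidation is wanted.
#'
#' @return an `embedding_backend`.
#' @export
identity_embedding_backend <- function() {
  embedding_backend("identity", function(labels) {
    u <- sort(unique(labels))
    diag(length(u))[match(labels, u), , drop = FALSE]
  })
}

#' Character n-gram hashing embedding backend
#'
#' Deterministic local embedding: counts character trigrams (on the
#' punctuation-stripped lowercased string, padded at the ends), hashes them
#' into `dim` buckets, and L2-normalizes. Orthographically close labels
#' ("antiviral" / "anti-viral") land close in cosine distance; unrelated
#' labels are far. The default text backend when no external embedding
#' service is configured.
#'
#' @param dim number of hash buckets (vector dimension).
#' @return an `embedding_backend`.
#' @export
ngram_embedding_backend <- function(dim = 256L) {
  embed_one <- function(label) {
    s <- gsub("[^a-z0-9]", "", tolower(label))
    s <- paste0("^", s, "$")
    v <- numeric(dim)
    if (nchar(s) >= 3L) {
      for (i in seq_len(nchar(s) - 2L)) {
        tri <- substr(s, i, i + 2L)
        h <- sum(utf8ToInt(tri) * c(1L, 131L, 17161L)) %% dim + 1L
        v[h] <- v[h] + 1
      }
    } else {
      v[sum(utf8ToInt(s)) %% dim + 1L] <- 1
    }
    v
  }
  embedding_backend("ngram-hash", function(labels) {
    t(vapply(labels, embed_one, numeric(dim)))
  })
}

#' Synonym-group test backend with planted geometry
#'
#' Places each synonym group on its own orthogonal axis and perturbs members
#' within the group by `delta`, so within-group cosine distances are of
#' order `delta` and between-group distances are of order 1. Used to verify
#' that the epsilon sweep recovers a planted grouping.
#'
#' @param groups named list: canonical term -> character vector of synonyms.
#' @param delta within-group perturbation scale.
#' @return an `embedding_backend`.
#' @export
synonym_embedding_backend <- function(groups, delta = 0.02) {
  members <- unlist(groups, use.names = FALSE)
  group_of <- rep(seq_along(groups), lengths(groups))
  names(group_of) <- members
  n_groups <- length(groups)
  dim <- n_groups + length(members)
  embedding_backend("synonym-test", function(labels) {
    m <- matrix(0, nrow = length(labels), ncol = dim)
    for (i in seq_along(labels)) {
      g <- group_of[[labels[i]]]
      if (is.null(g) || is.na(g)) {
        stop(sprintf("label '%s' unknown to the synonym backend", labels[i]),
             call. = FALSE)
      }
      m[i, g] <- 1
      m[i, n_groups + match(labels[i], members)] <- delta
    }
    m
  })
}

#' Embed a label vocabulary
#'
#' Runs the backend over the vocabulary and unit-normalizes each vector, so
#' cosine distance is `1 - x . y`.
#'
#' @param backend an [embedding_backend()].
#' @param labels nonempty character vector of unique labels.
#' @return numeric matrix, one unit row per label (row names = labels).
#' @export
embed_vocabulary <- function(backend, labels) {
  stopifnot(inherits(backend, "embedding_backend"))
  if (length(labels) == 0L) stop("empty vocabulary", call. = FALSE)
  if (anyDuplicated(labels)) stop("vocabulary must be duplicate-free", call. = FALSE)
  emb <- backend$embed(labels)
  if (!is.matrix(emb) || nrow(emb) != length(labels)) {
    stop(sprintf("backend '%s' returned a malformed embedding", backend$name),
         call. = FALSE)
  }
  norms <- sqrt(rowSums(emb^2))
  if (any(norms == 0)) {
    stop("backend produced a zero vector; vocabulary embedding must be total",
         call. = FALSE)
  }
  emb <- emb / norms
  rownames(emb) <- labels
  emb
}

cosine_distance_matrix <- function(x) {
  d <- 1 - tcrossprod(x / sqrt(rowSums(x^2)))
  d[d < 0] <- 0
  d
}

#' Density-based clustering on a precomputed distance matrix
#'
#' Classic DBSCAN: points with at least `min_samples` neighbours within
#' `eps` (the point itself included) are core; clusters are the connected
#' components of core points under eps-reachability, with border points
#' attached to the first cluster that reaches them. Noise points are
#' returned as singleton clusters so that rare but meaningful labels survive
#' consolidation.
#'
#' @param d symmetric distance matrix.
#' @param eps neighbourhood radius.
#' @param min_samples minimum neighbourhood size for a core point.
#' @return integer cluster assignment vector (length nrow(d)).
#' @export
dbscan_assign <- function(d, eps, min_samples = 2L) {
  n <- nrow(d)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(nb) >= min_samples
  cl <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (cl[i] != 0L || !core[i]) next
    next_id <- next_id + 1L
    cl[i] <- next_id
    queue <- i
    while (length(queue) > 0L) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      for (q in nb[[j]]) {
        if (cl[q] == 0L) {
          cl[q] <- next_id
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  noise <- cl == 0L
  if (any(noise)) cl[noise] <- next_id + seq_len(sum(noise))
  cl
}

#' Epsilon sweep for density clustering of label embeddings
#'
#' Runs density clustering at each epsilon on an ascending grid and selects
#' the largest epsilon under which no sentinel pair of labels shares a
#' cluster. The sentinels operationalize "cluster quality deterioration":
#' terms like antiviral / antibacterial / antifungal are semantically close
#' yet must never be merged. If every epsilon violates a sentinel, the
#' smallest-epsilon model is returned with a warning flag.
#'
#' @param embeddings unit-row matrix from [embed_vocabulary()].
#' @param eps_grid ascending numeric grid of epsilon values.
#' @param min_samples DBSCAN core threshold (default 2: any mutually close
#'   pair forms a cluster).
#' @param sentinel_pairs list of length-2 character vectors of labels that
#'   must stay in different clusters.
#' @param metric `"cosine"` (default, on unit rows) or `"euclidean"`.
#' @return a `cluster_model`: `epsilon`, `min_samples`, `assignments`
#'   (named integer vector), `n_clusters`, `sentinel_ok`, plus the sweep
#'   `trace` data.frame (eps, n_clusters, violations).
#' @export
sweep_dbscan <- function(embeddings, eps_grid, min_samples = 2L,
                         sentinel_pairs = list(),
                         metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  if (is.unsorted(eps_grid, strictly = FALSE)) {
    stop("`eps_grid` must be ascending", call. = FALSE)
  }
  labels <- rownames(embeddings)
  if (is.null(labels)) stop("embeddings must carry label row names", call. = FALSE)
  for (p in sentinel_pairs) {
    missing <- setdiff(p, labels)
    if (length(missing) > 0L) {
      stop(sprintf("sentinel label(s) not in vocabulary: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  d <- if (metric == "cosine") cosine_distance_matrix(embeddings)
       else as.matrix(stats::dist(embeddings))
  sweep <- lapply(eps_grid, function(eps) {
    cl <- dbscan_assign(d, eps, min_samples)
    viol <- sum(vapply(sentinel_pairs, function(p) {
      cl[match(p[1], labels)] == cl[match(p[2], labels)]
    }, logical(1)))
    list(eps = eps, cl = cl, n_clusters = length(unique(cl)), violations = viol)
  })
  trace <- data.frame(
    eps = vapply(sweep, `[[`, numeric(1), "eps"),
    n_clusters = vapply(sweep, `[[`, integer(1), "n_clusters"),
    violations = vapply(sweep, `[[`, numeric(1), "violations")
  )
  ok <- trace$violations == 0
  if (any(ok)) {
    pick <- max(which(ok))
    sentinel_ok <- TRUE
  } else {
    pick <- 1L
    sentinel_ok <- FALSE
    warning("no epsilon in the grid separates all sentinel pairs; returning the smallest-epsilon model",
            call. = FALSE)
  }
  chosen <- sweep[[pick]]
  structure(list(
    epsilon = chosen$eps,
    min_samples = as.integer(min_samples),
    assignments = stats::setNames(chosen$cl, labels),
    n_clusters = chosen$n_clusters,
    sentinel_ok = sentinel_ok,
    metric = metric,
    trace = trace
  ), class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> eps=%.4g (%s), %d labels -> %d clusters%s\n",
              x$epsilon, x$metric, length(x$assignments), x$n_clusters,
              if (x$sentinel_ok) "" else " [sentinel warning]"))
  invisible(x)
}

#' Summarize clusters into a consolidation map
#'
#' Gives each cluster one canonical label. The default deterministic rule
#' picks the member with the highest corpus abundance, breaking ties
#' lexicographically; singleton (noise) labels map to themselves. An LLM
#' summarizer can be substituted through `summarizer`, receiving the member
#' labels and returning one string.
#'
#' @param model a `cluster_model` from [sweep_dbscan()].
#' @param abundance named numeric vector of label abundances (molecule
#'   counts); missing labels count 0.
#' @param summarizer optional function(members, abundances) -> canonical
#'   label, replacing the frequency rule.
#' @return a `consolidation_map` data.frame (`raw_label`,
#'   `canonical_label`, `cluster_id`).
#' @export
summarize_clusters <- function(model, abundance = NULL, summarizer = NULL) {
  stopifnot(inherits(model, "cluster_model"))
  labels <- names(model$assignments)
  ab <- stats::setNames(rep(0, length(labels)), labels)
  if (!is.null(abundance)) {
    common <- intersect(names(abundance), labels)
    ab[common] <- abundance[common]
  }
  rows <- lapply(split(labels, model$assignments), function(members) {
    stopifnot(length(members) > 0L)
    canonical <- if (!is.null(summarizer)) {
      summarizer(members, ab[members])
    } else {
      best <- ab[members] == max(ab[members])
      min(sort(members[best]))
    }
    data.frame(raw_label = sort(members), canonical_label = canonical,
               stringsAsFactors = FALSE)
  })
  ids <- rep(as.integer(names(rows)), vapply(rows, nrow, integer(1)))
  out <- do.call(rbind, rows)
  out$cluster_id <- ids
  out <- out[order(out$raw_label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("consolidation_map", "data.frame")
  out
}

#' Remove a structural-terminology cluster from a consolidation map
#'
#' Patent text yields large clusters of pure structural nomenclature
#' (methyl, phenyl, ...) that carry no functional information; mappings
#' whose canonical label or cluster id is flagged are deleted. Molecules
#' keep their other labels; raw labels removed here are recorded so that
#' [apply_consolidation()] can silently drop them.
#'
#' @param map a `consolidation_map`.
#' @param stoplist canonical labels to remove.
#' @param cluster_ids cluster ids to remove.
#' @return the pruned map, with attribute `removed_labels` (raw labels).
#' @export
remove_structural_term_cluster <- function(map, stoplist = character(0),
                                           cluster_ids = integer(0)) {
  stopifnot(inherits(map, "consolidation_map"))
  drop <- map$canonical_label %in% stoplist | map$cluster_id %in% cluster_ids
  removed <- union(attr(map, "removed_labels") %||% character(0),
                   map$raw_label[drop])
  out <- map[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_labels") <- removed
  class(out) <- c("consolidation_map", "data.frame")
  out
}

#' Rewrite per-molecule labels through a consolidation map
#'
#' Maps every cleaned label to its canonical form and deduplicates per
#' molecule. Labels recorded as removed by
#' [remove_structural_term_cluster()] are dropped; any other label missing
#' from the map is a hard error (the map must be total over the
#' vocabulary). Molecules left with no labels are retained in the dataset
#' and counted.
#'
#' @param cleaned data.frame (`molecule_id`, `label`) from [clean_labels()].
#' @param map a `consolidation_map`.
#' @param molecule_ids optional molecule universe (kept even if unlabeled).
#' @return an unfiltered [chef_dataset()] with attribute
#'   `n_empty_molecules`.
#' @export
apply_consolidation <- function(cleaned, map, molecule_ids = NULL) {
  stopifnot(inherits(map, "consolidation_map"))
  removed <- attr(map, "removed_labels") %||% character(0)
  idx <- match(cleaned$label, map$raw_label)
  unmapped <- is.na(idx) & !(cleaned$label %in% removed)
  if (any(unmapped)) {
    stop(sprintf("consolidation map is not total: no mapping for %s",
                 paste(utils::head(unique(cleaned$label[unmapped]), 5L),
                       collapse = ", ")), call. = FALSE)
  }
  keep <- !is.na(idx)
  pairs <- data.frame(
    molecule_id = cleaned$molecule_id[keep],
    label = map$canonical_label[idx[keep]],
    stringsAsFactors = FALSE
  )
  universe <- molecule_ids %||% sort(unique(cleaned$molecule_id))
  ds <- chef_dataset(unique(pairs), molecule_ids = universe)
  n_empty <- sum(Matrix::rowSums(ds$incidence) == 0)
  attr(ds, "n_empty_molecules") <- n_empty
  ds
}

#' Drop rare labels from a dataset
#'
#' Labels carried by fewer than `min_molecules` molecules are removed (a
#' label on exactly `min_molecules` molecules is kept); molecules left with
#' zero labels are retained and counted. Rare labels lack the statistical
#' support needed by the downstream tests and classifiers.
#'
#' @param dataset a `chef_dataset`.
#' @param min_molecules abundance threshold (default 50).
#' @return the filtered `chef_dataset` with attribute `n_empty_molecules`.
#' @export
filter_rare_labels <- function(dataset, min_molecules = 50L) {
  stopifnot(inherits(dataset, "chef_dataset"))
  keep <- dataset$labels[dataset$abundance >= min_molecules]
  pairs <- dataset_pairs(dataset)
  pairs <- pairs[pairs$label %in% keep, , drop = FALSE]
  ds <- chef_dataset(pairs, molecule_ids = dataset$molecule_ids,
                     labels = keep)
  attr(ds, "n_empty_molecules") <- sum(Matrix::rowSums(ds$incidence) == 0)
  ds
}

#' Run the whole consolidation stage
#'
#' Convenience wrapper: embed the cleaned vocabulary, sweep epsilon,
#' summarize clusters against corpus abundance, remove a structural-term
#' stoplist, remap, and filter rare labels.
#'
#' @param cleaned data.frame (`molecule_id`, `label`).
#' @param backend an [embedding_backend()].
#' @param eps_grid epsilon grid for [sweep_dbscan()].
#' @param min_samples DBSCAN core threshold.
#' @param sentinel_pairs sentinel label pairs (pairs absent from the
#'   vocabulary are ignored).
#' @param stoplist canonical labels to remove as structural terms.
#' @param min_molecules abundance threshold for [filter_rare_labels()].
#' @param molecule_ids optional molecule universe.
#' @return list: `dataset` (filtered), `unfiltered`, `map`, `model`.
#' @export
consolidate_vocabulary <- function(cleaned, backend,
                                   eps_grid = seq(0.05, 0.6, by = 0.05),
                                   min_samples = 2L,
                                   sentinel_pairs = list(
                                     c("antiviral", "antibacterial"),
                                     c("antiviral", "antifungal"),
                                     c("antibacterial", "antifungal")
                                   ),
                                   stoplist = character(0),
                                   min_molecules = 50L,
                                   molecule_ids = NULL) {
  vocab <- sort(unique(cleaned$label))
  sentinel_pairs <- Filter(function(p) all(p %in% vocab), sentinel_pairs)
  emb <- embed_vocabulary(backend, vocab)
  model <- sweep_dbscan(emb, eps_grid, min_samples, sentinel_pairs)
  abundance <- table(unique(cleaned)[, "label"])
  map <- summarize_clusters(model, stats::setNames(as.numeric(abundance),
                                                   names(abundance)))
  map <- remove_structural_term_cluster(map, stoplist = stoplist)
  unfiltered <- apply_consolidation(cleaned, map, molecule_ids = molecule_ids)
  dataset <- filter_rare_labels(unfiltered, min_molecules = min_molecules)
  list(dataset = dataset, unfiltered = unfiltered, map = map, model = model)
}
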