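#' Build the label co-occurrence graph
#'
#' Nodes are the dataset's labels (zero-degree labels included); an edge
#' between two labels is weighted by the number of molecules carrying both,
#' so a molecule with k labels contributes 1 to each of its C(k,2) pairs.
#' The weight conservation identity
#' `sum of edge weights = sum over molecules of C(k, 2)` is asserted on
#' every build.
#'
#' @param dataset a `chef_dataset`.
#' @return an igraph graph with vertex attributes `abundance`, `degree`,
#'   `weighted_degree` and edge attribute `weight`.
#' @export
build_cooccurrence_graph <- function(dataset) {
  stopifnot(inherits(dataset, "chef_dataset"))
  x <- dataset$incidence
  co <- Matrix::crossprod(x)        # label x label co-occurrence counts
  Matrix::diag(co) <- 0
  k <- Matrix::rowSums(x)
  expected <- sum(choose(k, 2))
  total <- sum(co) / 2
  if (!isTRUE(all.equal(total, expected))) {
    stop(sprintf("co-occurrence weight conservation violated: %g != %g",
                 total, expected), call. = FALSE)
  }
  g <- igraph::graph_from_adjacency_matrix(as.matrix(co), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$abundance <- as.numeric(dataset$abundance[igraph::V(g)$name])
  igraph::V(g)$degree <- igraph::degree(g)
  igraph::V(g)$weighted_degree <- igraph::strength(g)
  g$n_molecules <- length(dataset$molecule_ids)
  g
}

#' Modularity community detection on the label graph
#'
#' Louvain-style modularity maximization at a given resolution, seeded for
#' reproducibility. Community structure on co-occurrence graphs is
#' inherently heuristic; the count of communities should be treated as
#' stochastic across seeds.
#'
#' @param graph co-occurrence graph from [build_cooccurrence_graph()].
#' @param resolution modularity resolution (default 0.5; smaller values
#'   merge into fewer, broader communities).
#' @param seed RNG seed.
#' @return a `community_partition`: `membership` (named integer),
#'   `resolution`, `modularity`, `n_communities`.
#' @export
detect_communities <- function(graph, resolution = 0.5, seed = 1L) {
  if (igraph::vcount(graph) == 0L) {
    return(structure(list(membership = integer(0), resolution = resolution,
                          modularity = NA_real_, n_communities = 0L),
                     class = "community_partition"))
  }
  cl <- with_seed(seed, {
    igraph::cluster_louvain(graph, weights = igraph::E(graph)$weight,
                            resolution = resolution)
  })
  memb <- igraph::membership(cl)
  structure(list(
    membership = stats::setNames(as.integer(memb), names(memb)),
    resolution = resolution,
    modularity = igraph::modularity(graph, memb,
                                    weights = igraph::E(graph)$weight),
    n_communities = length(unique(memb))
  ), class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d nodes -> %d communities (resolution %.2f, modularity %.3f)\n",
              length(x$membership), x$n_communities, x$resolution, x$modularity))
  invisible(x)
}

#' Most frequently co-occurring neighbour labels
#'
#' Among the label's graph neighbours with abundance strictly below
#' `abundance_cap`, the `k` with the highest co-occurrence edge weight
#' (ties broken lexicographically). The cap guards the downstream
#' coherence test: hyper-abundant neighbours would blanket structure space
#' and force maximum similarities to 1.
#'
#' @param graph co-occurrence graph.
#' @param label query label (must be a node).
#' @param k neighbours to return (default 10).
#' @param abundance_cap strict upper bound on neighbour abundance
#'   (default 1000).
#' @return character vector of up to `k` labels (possibly empty).
#' @export
top_cooccurring_labels <- function(graph, label, k = 10L, abundance_cap = 1000L) {
  if (!label %in% igraph::V(graph)$name) {
    stop(sprintf("label '%s' is not a node of the graph", label), call. = FALSE)
  }
  edges <- igraph::incident(graph, label)
  if (length(edges) == 0L) return(character(0))
  ends <- igraph::ends(graph, edges)
  nbr <- ifelse(ends[, 1] == label, ends[, 2], ends[, 1])
  w <- igraph::E(graph)$weight[as.integer(edges)]
  ab <- igraph::V(graph)$abundance[match(nbr, igraph::V(graph)$name)]
  ok <- ab < abundance_cap
  nbr <- nbr[ok]
  w <- w[ok]
  if (length(nbr) == 0L) return(character(0))
  ord <- order(-w, nbr)
  utils::head(nbr[ord], k)
}

#' Structure-space coherence test for one label's text neighbourhood
#'
#' Target set: the union of molecules carrying any of the label's top
#' co-occurring neighbour labels. Observed statistic: for each molecule
#' carrying the label, the maximum Tanimoto similarity to the target set
#' (the query molecule itself excluded wherever it appears). Null: the same
#' with a uniformly random molecule set of the target set's size. Two-sided
#' Welch t-test; FDR is applied family-wide by the runner.
#'
#' @param label query label.
#' @param dataset a `chef_dataset`.
#' @param fingerprints a [fingerprint_matrix()].
#' @param graph co-occurrence graph.
#' @param k,abundance_cap passed to [top_cooccurring_labels()].
#' @param seed RNG seed for the null draw.
#' @return one-row data.frame (label, n, n_neighbors, target_size,
#'   mean_obs, mean_null, t_stat, p_value), or a `coherence_skip` object
#'   carrying the reason when the label has no eligible neighbours or fewer
#'   than two usable molecules.
#' @export
coherence_test <- function(label, dataset, fingerprints, graph,
                           k = 10L, abundance_cap = 1000L, seed = 1L) {
  skip <- function(reason) {
    structure(list(label = label, reason = reason), class = "coherence_skip")
  }
  mols <- label_molecules(dataset, label)
  if (length(mols) < 2L) {
    return(skip("fewer than 2 molecules"))
  }
  nbrs <- top_cooccurring_labels(graph, label, k = k,
                                 abundance_cap = abundance_cap)
  if (length(nbrs) == 0L) {
    return(skip("no eligible co-occurring neighbour"))
  }
  target <- sort(unique(unlist(lapply(nbrs, label_molecules,
                                      dataset = dataset))))
  observed <- max_sim_to_set(fingerprints[mols], fingerprints[target])
  observed <- observed[!is.na(observed)]
  if (length(observed) < 2L) {
    return(skip("target set empty after self-exclusion"))
  }
  null_vals <- with_seed(seed, {
    rand <- sample(dataset$molecule_ids, min(length(target),
                                             length(dataset$molecule_ids)))
    v <- max_sim_to_set(fingerprints[mols], fingerprints[rand])
    v[!is.na(v)]
  })
  ht <- welch_test(observed, null_vals)
  data.frame(
    label = label, n = length(mols), n_neighbors = length(nbrs),
    target_size = length(target),
    mean_obs = mean(observed), mean_null = mean(null_vals),
    t_stat = ht$t, p_value = ht$p, stringsAsFactors = FALSE
  )
}

#' Full text-landscape coherence analysis
#'
#' Builds the co-occurrence graph, detects modularity communities, runs
#' [coherence_test()] for every eligible label, and applies BH-FDR over the
#' tested family. Labels without eligible neighbours are excluded from the
#' FDR family and reported separately.
#'
#' @param dataset a filtered `chef_dataset`.
#' @param fingerprints a [fingerprint_matrix()].
#' @param alpha FDR level.
#' @param k,abundance_cap neighbourhood parameters.
#' @param resolution community-detection resolution.
#' @param seed run seed.
#' @return list: `results` (coherence table with q-values and significance,
#'   attribute `n_significant`), `graph`, `partition`, `skipped`
#'   (data.frame label/reason).
#' @export
run_landscape_analysis <- function(dataset, fingerprints, alpha = 0.05,
                                   k = 10L, abundance_cap = 1000L,
                                   resolution = 0.5, seed = 1L) {
  graph <- build_cooccurrence_graph(dataset)
  partition <- detect_communities(graph, resolution = resolution,
                                  seed = child_seed(seed, 0L))
  rows <- list()
  skipped <- list()
  for (i in seq_along(dataset$labels)) {
    lab <- dataset$labels[i]
    res <- coherence_test(lab, dataset, fingerprints, graph, k = k,
                          abundance_cap = abundance_cap,
                          seed = child_seed(seed, i))
    if (inherits(res, "coherence_skip")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(label = lab, reason = res$reason, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  results <- do.call(rbind, rows) %||% data.frame(
    label = character(0), n = integer(0), n_neighbors = integer(0),
    target_size = integer(0), mean_obs = numeric(0), mean_null = numeric(0),
    t_stat = numeric(0), p_value = numeric(0)
  )
  fdr <- fdr_correct(results$p_value, alpha)
  results$q_value <- fdr$q_values
  results$significant <- fdr$flags
  rownames(results) <- NULL
  attr(results, "n_significant") <- sum(results$significant)
  attr(results, "alpha") <- alpha
  list(
    results = results,
    graph = graph,
    partition = partition,
    skipped = do.call(rbind, skipped) %||%
      data.frame(label = character(0), reason = character(0))
  )
}

#' Export the landscape graph as GraphML
#'
#' Node attributes (abundance, degree, weighted degree, community) and edge
#' weights are carried so the file opens ready for Gephi-style layout.
#'
#' @param graph co-occurrence graph.
#' @param partition optional `community_partition` to attach.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_landscape_graphml <- function(graph, partition = NULL, path) {
  if (!is.null(partition)) {
    igraph::V(graph)$community <-
      as.integer(partition$membership[igraph::V(graph)$name])
  }
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export the landscape graph as GEXF
#'
#' Minimal GEXF 1.2 writer (nodes with abundance/degree/community
#' attributes, weighted undirected edges) for interoperability with Gephi.
#'
#' @param graph co-occurrence graph.
#' @param partition optional `community_partition`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_landscape_gexf <- function(graph, partition = NULL, path) {
  nodes <- igraph::V(graph)$name
  community <- if (!is.null(partition)) {
    as.integer(partition$membership[nodes])
  } else rep(NA_integer_, length(nodes))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<gexf xmlns=\"http://www.gexf.net/1.2draft\" version=\"1.2\">",
    "  <graph mode=\"static\" defaultedgetype=\"undirected\">",
    "    <attributes class=\"node\">",
    "      <attribute id=\"0\" title=\"abundance\" type=\"double\"/>",
    "      <attribute id=\"1\" title=\"degree\" type=\"integer\"/>",
    "      <attribute id=\"2\" title=\"weighted_degree\" type=\"double\"/>",
    "      <attribute id=\"3\" title=\"community\" type=\"integer\"/>",
    "    </attributes>",
    "    <nodes>"
  ), con)
  for (i in seq_along(nodes)) {
    writeLines(sprintf(
      paste0("      <node id=\"%d\" label=\"%s\"><attvalues>",
             "<attvalue for=\"0\" value=\"%g\"/>",
             "<attvalue for=\"1\" value=\"%d\"/>",
             "<attvalue for=\"2\" value=\"%g\"/>",
             "%s</attvalues></node>"),
      i - 1L, xml_escape(nodes[i]),
      igraph::V(graph)$abundance[i], igraph::V(graph)$degree[i],
      igraph::V(graph)$weighted_degree[i],
      if (is.na(community[i])) "" else
        sprintf("<attvalue for=\"3\" value=\"%d\"/>", community[i])
    ), con)
  }
  writeLines("    </nodes>", con)
  writeLines("    <edges>", con)
  if (igraph::ecount(graph) > 0L) {
    ends <- igraph::ends(graph, igraph::E(graph))
    w <- igraph::E(graph)$weight
    for (e in seq_len(nrow(ends))) {
      writeLines(sprintf(
        "      <edge id=\"%d\" source=\"%d\" target=\"%d\" weight=\"%g\"/>",
        e - 1L, match(ends[e, 1], nodes) - 1L, match(ends[e, 2], nodes) - 1L,
        w[e]), con)
    }
  }
  writeLines(c("    </edges>", "  </graph>", "</gexf>"), con)
  invisible(path)
}
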