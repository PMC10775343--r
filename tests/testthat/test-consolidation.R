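test_that("embedding a vocabulary yields one unit row per label", {
  emb <- embed_vocabulary(ngram_embedding_backend(64),
                          c("antiviral", "antibacterial", "kinase"))
  expect_equal(dim(emb), c(3, 64))
  expect_equal(unname(sqrt(rowSums(emb^2))), rep(1, 3))
  emb2 <- embed_vocabulary(ngram_embedding_backend(64),
                           c("antiviral", "antibacterial", "kinase"))
  expect_identical(emb, emb2)
  expect_error(embed_vocabulary(ngram_embedding_backend(64), character(0)),
               "empty")
  expect_error(embed_vocabulary(ngram_embedding_backend(64), c("a", "a")),
               "duplicate")
})

test_that("orthographically close labels embed close under the n-gram backend", {
  emb <- embed_vocabulary(ngram_embedding_backend(256),
                          c("antiviral", "anti-viral", "electroluminescence"))
  d <- chemfunc:::cosine_distance_matrix(emb)
  expect_lt(d["antiviral", "anti-viral"], 0.05)
  expect_gt(d["antiviral", "electroluminescence"], 0.5)
})

test_that("density clustering recovers tight groups at the right epsilon (2D geometry)", {
  pts <- matrix(c(0, 0, 0, 0.1, 5, 0, 5, 0.1), ncol = 2, byrow = TRUE)
  rownames(pts) <- paste0("p", 1:4)
  d <- as.matrix(dist(pts))
  cl_small <- dbscan_assign(d, eps = 0.2, min_samples = 2)
  expect_equal(length(unique(cl_small)), 2)
  expect_equal(cl_small[1], cl_small[2])
  expect_equal(cl_small[3], cl_small[4])
  cl_big <- dbscan_assign(d, eps = 6, min_samples = 2)
  expect_equal(length(unique(cl_big)), 1)
  # isolated points become singleton clusters
  cl_none <- dbscan_assign(d, eps = 0.01, min_samples = 2)
  expect_equal(length(unique(cl_none)), 4)
})

test_that("the epsilon sweep honors sentinel pairs and records a trace", {
  pts <- matrix(c(0, 0, 0, 0.1, 5, 0, 5, 0.1), ncol = 2, byrow = TRUE)
  rownames(pts) <- c("a1", "a2", "b1", "b2")
  model <- sweep_dbscan(pts, eps_grid = c(0.2, 1, 6), min_samples = 2,
                        sentinel_pairs = list(c("a1", "b1")),
                        metric = "euclidean")
  expect_true(model$sentinel_ok)
  expect_lt(model$epsilon, 5)       # below the between-group gap
  expect_equal(model$n_clusters, 2)
  expect_equal(nrow(model$trace), 3)
  # cluster counts do not increase with epsilon on this geometry
  expect_true(all(diff(model$trace$n_clusters) <= 0))
  # sentinel that can never be satisfied -> smallest epsilon with warning
  expect_warning(
    bad <- sweep_dbscan(pts, eps_grid = c(6, 7), min_samples = 2,
                        sentinel_pairs = list(c("a1", "b1")),
                        metric = "euclidean"),
    "sentinel")
  expect_false(bad$sentinel_ok)
  expect_equal(bad$epsilon, 6)
})

test_that("a planted synonym geometry is recovered exactly by the sweep", {
  groups <- list(antiviral = c("antiviral", "anti-viral", "antivirus"),
                 kinase = c("kinase", "kinases-like"),
                 solo = "electroluminescence")
  backend <- synonym_embedding_backend(groups, delta = 0.02)
  vocab <- unlist(groups, use.names = FALSE)
  emb <- embed_vocabulary(backend, vocab)
  model <- sweep_dbscan(emb, eps_grid = seq(0.01, 0.9, by = 0.02),
                        min_samples = 2,
                        sentinel_pairs = list(c("antiviral", "kinase")))
  groups_got <- split(names(model$assignments), model$assignments)
  expect_setequal(
    unname(vapply(groups_got, function(g) paste(sort(g), collapse = "|"),
                  character(1))),
    unname(vapply(groups, function(g) paste(sort(g), collapse = "|"),
                  character(1)))
  )
})

test_that("cluster summarization follows the abundance-then-lexicographic rule", {
  assign <- stats::setNames(c(1L, 1L, 2L, 3L, 3L),
                            c("antiviral", "anti-viral", "electroluminescence",
                              "x", "a"))
  model <- structure(list(assignments = assign, epsilon = 0.1,
                          min_samples = 2L, n_clusters = 3L,
                          sentinel_ok = TRUE, metric = "cosine"),
                     class = "cluster_model")
  map <- summarize_clusters(model, abundance = c(antiviral = 120,
                                                 `anti-viral` = 4,
                                                 x = 5, a = 5))
  expect_identical(map$canonical_label[map$raw_label == "anti-viral"], "antiviral")
  expect_identical(map$canonical_label[map$raw_label == "electroluminescence"],
                   "electroluminescence")  # singleton maps to itself
  expect_identical(map$canonical_label[map$raw_label == "x"], "a")  # tie -> lexicographic
})

test_that("structural-term removal deletes flagged mappings only", {
  assign <- stats::setNames(c(1L, 1L, 2L, 3L), c("methyl", "phenyl", "antiviral", "kinase"))
  model <- structure(list(assignments = assign, epsilon = 0.1, min_samples = 2L,
                          n_clusters = 3L, sentinel_ok = TRUE, metric = "cosine"),
                     class = "cluster_model")
  map <- summarize_clusters(model, abundance = c(methyl = 50, phenyl = 10))
  pruned <- remove_structural_term_cluster(map, stoplist = "methyl")
  expect_setequal(pruned$raw_label, c("antiviral", "kinase"))
  expect_setequal(attr(pruned, "removed_labels"), c("methyl", "phenyl"))
  unchanged <- remove_structural_term_cluster(map)
  expect_equal(nrow(unchanged), nrow(map))
})

test_that("consolidation rewrites, deduplicates and keeps emptied molecules", {
  cleaned <- data.frame(
    molecule_id = c("m1", "m1", "m2", "m3"),
    label = c("anti-viral", "antiviral", "kinase", "methyl"),
    stringsAsFactors = FALSE
  )
  map <- structure(data.frame(
    raw_label = c("anti-viral", "antiviral", "kinase", "methyl"),
    canonical_label = c("antiviral", "antiviral", "kinase", "methyl"),
    cluster_id = c(1L, 1L, 2L, 3L), stringsAsFactors = FALSE
  ), class = c("consolidation_map", "data.frame"))
  map <- remove_structural_term_cluster(map, stoplist = "methyl")
  ds <- apply_consolidation(cleaned, map)
  expect_equal(sum(ds$incidence[, "antiviral"]), 1)  # deduplicated
  expect_identical(attr(ds, "n_empty_molecules"), 1L)  # m3 retained, empty
  expect_true("m3" %in% ds$molecule_ids)
  # a label missing from the map (and not removed) is a hard error
  bad <- rbind(cleaned, data.frame(molecule_id = "m4", label = "unmapped"))
  expect_error(apply_consolidation(bad, map), "not total")
})

test_that("rare-label filter drops strictly below the threshold", {
  pairs <- do.call(rbind, lapply(
    list(c("a", 3), c("b", 50), c("c", 49), c("d", 200)),
    function(x) data.frame(molecule_id = paste0("m", seq_len(as.integer(x[2]))),
                           label = x[1], stringsAsFactors = FALSE)))
  ds <- chef_dataset(pairs)
  filtered <- filter_rare_labels(ds, min_molecules = 50)
  expect_setequal(filtered$labels, c("b", "d"))
  # threshold 1 is the identity on the vocabulary
  expect_setequal(filter_rare_labels(ds, 1)$labels, ds$labels)
  expect_equal(length(filter_rare_labels(ds, 1)$molecule_ids),
               length(ds$molecule_ids))
})

test_that("identity backend makes the full consolidation stage the identity", {
  corpus <- roundtrip_corpus()
  cleaned <- clean_labels(extract_labels(
    mock_extraction_backend(corpus$planted_labels), corpus$patents))
  cons <- consolidate_vocabulary(cleaned, identity_embedding_backend(),
                                 min_molecules = 1,
                                 molecule_ids = corpus$molecules$molecule_id)
  expect_setequal(cons$dataset$labels, unique(corpus$truth$label))
  got <- dataset_pairs(cons$dataset)
  truth <- corpus$truth[order(corpus$truth$molecule_id, corpus$truth$label), ]
  expect_identical(paste(got$molecule_id, got$label),
                   paste(truth$molecule_id, truth$label))
  # consolidation never grows the vocabulary or changes molecule count
  expect_lte(length(cons$dataset$labels), length(unique(cleaned$label)))
  expect_equal(length(cons$dataset$molecule_ids), nrow(corpus$molecules))
})
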