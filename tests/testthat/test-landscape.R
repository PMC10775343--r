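test_that("co-occurrence edges count molecules carrying both labels", {
  pairs <- data.frame(
    molecule_id = c("m1", "m1", "m2", "m2", "m3", "m3"),
    label = c("a", "b", "a", "b", "a", "c"),
    stringsAsFactors = FALSE
  )
  g <- build_cooccurrence_graph(chef_dataset(pairs))
  w <- function(x, y) {
    e <- igraph::get_edge_ids(g, c(x, y))
    if (e == 0) 0 else igraph::E(g)$weight[e]
  }
  expect_equal(w("a", "b"), 2)
  expect_equal(w("a", "c"), 1)
  expect_equal(w("b", "c"), 0)
  expect_equal(igraph::V(g)$abundance[match("a", igraph::V(g)$name)], 3)
})

test_that("single-labeled molecules give an edgeless graph with all labels as nodes", {
  pairs <- data.frame(molecule_id = paste0("m", 1:4),
                      label = c("a", "b", "c", "a"), stringsAsFactors = FALSE)
  g <- build_cooccurrence_graph(chef_dataset(pairs))
  expect_equal(igraph::ecount(g), 0)
  expect_equal(igraph::vcount(g), 3)
})

test_that("edge weights conserve the per-molecule pair count on random incidence", {
  set.seed(7)
  for (rep in 1:3) {
    pairs <- unique(data.frame(
      molecule_id = sample(paste0("m", 1:20), 60, replace = TRUE),
      label = sample(letters[1:6], 60, replace = TRUE),
      stringsAsFactors = FALSE
    ))
    ds <- chef_dataset(pairs)
    g <- build_cooccurrence_graph(ds)  # conservation asserted internally
    k <- Matrix::rowSums(ds$incidence)
    expect_equal(sum(igraph::E(g)$weight), sum(choose(k, 2)))
  }
})

test_that("community detection resolves disconnected cliques and is seeded", {
  pairs <- do.call(rbind, lapply(1:2, function(b) {
    labs <- paste0("g", b, "_", 1:5)
    do.call(rbind, lapply(1:6, function(m) {
      data.frame(molecule_id = sprintf("m%d_%d", b, m), label = labs,
                 stringsAsFactors = FALSE)
    }))
  }))
  g <- build_cooccurrence_graph(chef_dataset(pairs))
  part <- detect_communities(g, resolution = 0.5, seed = 3)
  expect_equal(part$n_communities, 2)
  expect_gte(part$modularity, 0)  # beats the one-community partition
  part2 <- detect_communities(g, resolution = 0.5, seed = 3)
  expect_identical(part$membership, part2$membership)

  single <- build_cooccurrence_graph(chef_dataset(
    data.frame(molecule_id = "m1", label = "only")))
  expect_equal(detect_communities(single, seed = 1)$n_communities, 1)
})

test_that("top co-occurring labels rank by weight with a strict abundance cap", {
  mk <- function(label, n, ids) data.frame(molecule_id = ids[seq_len(n)],
                                           label = label,
                                           stringsAsFactors = FALSE)
  ids <- sprintf("m%04d", 1:1200)
  pairs <- rbind(
    mk("q", 30, ids), mk("b", 5, ids), mk("c", 5, ids), mk("d", 9, ids),
    mk("huge", 1000, ids)
  )
  ds <- chef_dataset(pairs)
  g <- build_cooccurrence_graph(ds)
  # neighbour at abundance exactly 1000 is excluded by the strict bound
  top <- top_cooccurring_labels(g, "q", k = 10, abundance_cap = 1000)
  expect_false("huge" %in% top)
  expect_setequal(top, c("b", "c", "d"))  # fewer than k -> all returned
  # weight then lexicographic tie-break
  expect_identical(top_cooccurring_labels(g, "q", k = 2, abundance_cap = 1000),
                   c("d", "b"))
  expect_error(top_cooccurring_labels(g, "nope"), "not a node")
})

test_that("twin labels on a shared scaffold test coherent; alien neighbours do not", {
  cfg <- synthetic_config(n_scaffolds = 6, members_per_scaffold = 25,
                          n_bits = 512, flip_rate = 0.02,
                          n_planted_labels = 12, labels_per_scaffold = 2,
                          n_background_labels = 0, label_noise = 0, seed = 41)
  corpus <- generate_corpus(cfg, with_patents = FALSE)
  ds <- truth_dataset(corpus)
  g <- build_cooccurrence_graph(ds)
  fp <- corpus$fingerprints
  lab <- corpus$planted_labels[1]
  res <- coherence_test(lab, ds, fp, g, seed = 5)
  expect_gt(res$mean_obs, res$mean_null)
  expect_lt(res$p_value, 0.01)
  # rewire the incidence so the query label's only co-occurring neighbour
  # lives on a structurally alien scaffold (bridged by one alien molecule
  # that also carries the query label): coherence collapses
  twin <- corpus$planted_labels[2]
  alien <- ds$molecule_ids[corpus$scaffold_of == 4]
  pairs <- dataset_pairs(ds)
  pairs <- pairs[!pairs$label %in% c(lab, twin), ]
  lab_mols <- label_molecules(ds, lab)
  pairs <- rbind(pairs,
                 data.frame(molecule_id = c(lab_mols, alien[1]), label = lab),
                 data.frame(molecule_id = alien, label = twin))
  ds2 <- chef_dataset(pairs, molecule_ids = ds$molecule_ids)
  g2 <- build_cooccurrence_graph(ds2)
  # every co-occurring neighbour now lives on the alien scaffold
  nbr_mols <- unique(unlist(lapply(top_cooccurring_labels(g2, lab),
                                   label_molecules, dataset = ds2)))
  expect_true(all(corpus$scaffold_of[nbr_mols] == 4))
  res2 <- coherence_test(lab, ds2, fp, g2, seed = 5)
  expect_lt(res2$t_stat, 0)
  expect_lt(res2$mean_obs, res2$mean_null)
})

test_that("labels without eligible neighbours are skipped with a reason", {
  pairs <- data.frame(molecule_id = paste0("m", 1:6),
                      label = rep("solo", 6), stringsAsFactors = FALSE)
  ds <- chef_dataset(pairs)
  m <- matrix(rbinom(6 * 64, 1, 0.2), nrow = 6,
              dimnames = list(paste0("m", 1:6), NULL))
  fp <- fingerprint_matrix(m, list(type = "test"))
  g <- build_cooccurrence_graph(ds)
  res <- coherence_test("solo", ds, fp, g, seed = 1)
  expect_s3_class(res, "coherence_skip")
  expect_match(res$reason, "neighbour")
  land <- run_landscape_analysis(ds, fp, seed = 1)
  expect_equal(nrow(land$results), 0)
  expect_equal(nrow(land$skipped), 1)
})

test_that("the landscape runner flags planted twins and controls background labels", {
  corpus <- study_corpus()
  ds <- truth_dataset(corpus)
  land <- run_landscape_analysis(ds, corpus$fingerprints, seed = 501)
  res <- land$results
  planted <- res[res$label %in% corpus$planted_labels, ]
  background <- res[res$label %in% corpus$background_labels, ]
  expect_gt(mean(planted$t_stat), mean(background$t_stat))
  expect_lte(sum(background$significant), 4)
  expect_true(all(names(land$partition$membership) %in% ds$labels))
  expect_equal(length(land$partition$membership), igraph::vcount(land$graph))
})

test_that("graph exports round-trip node and edge attributes", {
  pairs <- data.frame(
    molecule_id = c("m1", "m1", "m2", "m2", "m3", "m3"),
    label = c("a", "b", "a", "b", "b", "c"),
    stringsAsFactors = FALSE
  )
  ds <- chef_dataset(pairs)
  g <- build_cooccurrence_graph(ds)
  part <- detect_communities(g, seed = 1)
  dir <- withr::local_tempdir()
  gml <- file.path(dir, "landscape.graphml")
  write_landscape_graphml(g, part, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(back)$name, c("a", "b", "c"))
  expect_equal(sort(igraph::E(back)$weight), sort(igraph::E(g)$weight))
  expect_true(all(igraph::V(back)$community %in% part$membership))

  gexf <- file.path(dir, "landscape.gexf")
  write_landscape_gexf(g, part, gexf)
  doc <- xml2::read_xml(gexf)
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:node", ns)), 3)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:edge", ns)), 2)
})
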