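test_that("splitting is seeded, sized by rounding, and partitions the molecules", {
  ids <- sprintf("m%04d", 1:100)
  sp <- split_dataset(ids, test_fraction = 0.1, seed = 5)
  expect_length(sp$test, 10)
  expect_length(sp$train, 90)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp$test, split_dataset(ids, 0.1, seed = 5)$test)
  big <- sprintf("m%04d", 1:1000)
  expect_false(identical(split_dataset(big, 0.1, seed = 1)$test,
                         split_dataset(big, 0.1, seed = 2)$test))
  expect_error(split_dataset(ids, test_fraction = 0), "\\(0, 1\\)")
  expect_error(split_dataset(ids, test_fraction = 1.2), "\\(0, 1\\)")
})

test_that("ROC-AUC matches pROC and handles degenerate scorers", {
  set.seed(3)
  for (rep in 1:3) {
    y <- rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- rnorm(60)
    ours <- roc_auc(s, y)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)  # constant scorer
  expect_true(is.na(roc_auc(rnorm(5), rep(1, 5))))
})

test_that("PR-AUC equals hand-computed average precision on a known case", {
  # scores rank: pos, neg, pos, neg -> precisions 1/1 and 2/3 at the positives
  s <- c(0.9, 0.8, 0.7, 0.1)
  y <- c(1, 0, 1, 0)
  expect_equal(pr_auc(s, y), 0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(pr_auc(c(0.9, 0.8, 0.2), c(1, 1, 0)), 1)
  expect_true(is.na(pr_auc(rnorm(4), rep(0, 4))))
  # random scores on a balanced label sit near the positive prevalence
  set.seed(8)
  aps <- replicate(50, pr_auc(rnorm(100), rep(c(0, 1), 50)))
  expect_lt(abs(mean(aps) - 0.5), 0.05)
})

test_that("labels without both classes in training are masked, not fatal", {
  corpus <- roundtrip_corpus()
  ds <- truth_dataset(corpus)
  fp <- corpus$fingerprints
  sp <- split_dataset(ds, 0.2, seed = 2)
  # add a label with zero positives anywhere
  pairs <- rbind(dataset_pairs(ds),
                 data.frame(molecule_id = ds$molecule_ids[1], label = "ghost"))
  ds2 <- chef_dataset(pairs, molecule_ids = ds$molecule_ids)
  # force "ghost"'s only molecule into the test set
  sp2 <- sp
  if (!ds$molecule_ids[1] %in% sp2$test) {
    sp2$test <- c(sp2$test, ds$molecule_ids[1])
    sp2$train <- setdiff(sp2$train, ds$molecule_ids[1])
  }
  model <- train_multilabel(model_config("logistic", seed = 1), fp, ds2, sp2)
  expect_true("ghost" %in% model$masked_labels)
  probs <- predict_profiles(model, fp)
  expect_false("ghost" %in% colnames(probs))
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("logistic refits are deterministic and recover planted structure", {
  corpus <- roundtrip_corpus()
  ds <- truth_dataset(corpus)
  fp <- corpus$fingerprints
  sp <- split_dataset(ds, 0.2, seed = 6)
  # tiny training set: soften the full-scale ridge so per-label signal
  # survives for the cross-label profile check
  cfgm <- model_config("logistic", C = 0.1, seed = 4)
  m1 <- train_multilabel(cfgm, fp, ds, sp)
  m2 <- train_multilabel(cfgm, fp, ds, sp)
  p1 <- predict_profiles(m1, fp)
  p2 <- predict_profiles(m2, fp)
  expect_equal(unclass(p1), unclass(p2), tolerance = 1e-10)
  ev <- evaluate(p1, ds, sp)
  expect_gt(ev$macro_roc_auc, 0.9)  # zero-noise scaffold labels are learnable
  # a pure-scaffold training molecule ranks one of its own labels first
  mol <- sp$train[1]
  planted <- corpus$truth$label[corpus$truth$molecule_id == mol]
  expect_true(names(which.max(p1[mol, ])) %in% planted)
})

test_that("random-forest and feedforward families train and score probabilities", {
  corpus <- roundtrip_corpus()
  ds <- truth_dataset(corpus)
  fp <- corpus$fingerprints
  sp <- split_dataset(ds, 0.2, seed = 6)
  rf <- train_multilabel(model_config("random_forest", n_trees = 30, seed = 2),
                         fp, ds, sp)
  p_rf <- predict_profiles(rf, fp)
  expect_true(all(p_rf >= 0 & p_rf <= 1))
  expect_gt(evaluate(p_rf, ds, sp)$macro_roc_auc, 0.8)
  p_rf2 <- predict_profiles(
    train_multilabel(model_config("random_forest", n_trees = 30, seed = 2),
                     fp, ds, sp), fp)
  expect_equal(unclass(p_rf), unclass(p_rf2))  # seeded refit

  # small corpus: more epochs than the full-scale default so the tiny
  # network sees enough minibatches to converge
  nn <- train_multilabel(
    model_config("feedforward", hidden = c(32L, 16L), epochs = 60L, seed = 3),
    fp, ds, sp)
  p_nn <- predict_profiles(nn, fp)
  expect_true(all(p_nn >= 0 & p_nn <= 1))
  expect_gt(evaluate(p_nn, ds, sp)$macro_roc_auc, 0.8)
})

test_that("fingerprint spec mismatches are rejected by prediction", {
  corpus <- roundtrip_corpus()
  ds <- truth_dataset(corpus)
  sp <- split_dataset(ds, 0.2, seed = 1)
  model <- train_multilabel(model_config("logistic", seed = 1),
                            corpus$fingerprints, ds, sp)
  other <- fingerprint_matrix(
    matrix(0L, 2, 64, dimnames = list(c("a", "b"), NULL)),
    spec = list(type = "other", n_bits = 64L))
  expect_error(predict_profiles(model, other), "spec mismatch")
})

test_that("test-set labels never influence training (no leakage)", {
  corpus <- roundtrip_corpus()
  ds <- truth_dataset(corpus)
  fp <- corpus$fingerprints
  sp <- split_dataset(ds, 0.2, seed = 9)
  base <- predict_profiles(
    train_multilabel(model_config("logistic", seed = 2), fp, ds, sp), fp)
  flipped <- ds
  inc <- as.matrix(ds$incidence)
  inc[sp$test, ] <- 1 - inc[sp$test, ]
  flipped$incidence <- Matrix::Matrix(inc, sparse = TRUE)
  flipped$abundance <- stats::setNames(Matrix::colSums(flipped$incidence),
                                       flipped$labels)
  alt <- predict_profiles(
    train_multilabel(model_config("logistic", seed = 2), fp, flipped, sp), fp)
  expect_equal(base[sp$train, ], alt[sp$train, ], tolerance = 1e-10)
})

test_that("ranked retrieval is deterministic, prefix-consistent, and recovers scaffolds", {
  corpus <- roundtrip_corpus()
  ds <- truth_dataset(corpus)
  fp <- corpus$fingerprints
  sp <- split_dataset(ds, 0.2, seed = 6)
  model <- train_multilabel(model_config("logistic", seed = 4), fp, ds, sp)
  probs <- predict_profiles(model, fp)
  lab <- corpus$planted_labels[1]
  top5 <- query_top_molecules(probs, lab, k = 5)
  top8 <- query_top_molecules(probs, lab, k = 8)
  expect_identical(top5$molecule_id, top8$molecule_id[1:5])
  expect_equal(top5$rank, 1:5)
  # top-k molecules come from the label's scaffold
  scaf <- unique(corpus$scaffold_of[label_molecules(ds, lab)])
  expect_gte(mean(corpus$scaffold_of[top8$molecule_id] == scaf), 0.8)
  # k larger than the subset returns the whole subset
  sub <- sp$test[1:4]
  expect_equal(nrow(query_top_molecules(probs, lab, k = 99, subset = sub)), 4)
  expect_error(query_top_molecules(probs, "not-a-label"), "not scored")
})

test_that("SMILES-track models annotate molecules with their planted label on top", {
  corpus <- smiles_corpus()
  recs <- canonicalize_molecules(corpus$molecules)
  fp <- compute_fingerprints(recs)
  truth <- corpus$truth[corpus$truth$molecule_id %in% recs$molecule_id, ]
  ds <- chef_dataset(truth, molecule_ids = recs$molecule_id)
  sp <- split_dataset(ds, 0.2, seed = 3)
  model <- train_multilabel(model_config("logistic", C = 0.1, seed = 5),
                            fp, ds, sp)
  mol <- sp$train[2]
  planted <- corpus$truth$label[corpus$truth$molecule_id == mol][1]
  prof <- annotate_molecule(model, recs$smiles[recs$molecule_id == mol])
  expect_identical(prof$label[1], planted)
  expect_equal(nrow(prof), length(model$labels))
  prof2 <- annotate_molecule(model, recs$smiles[recs$molecule_id == mol])
  expect_identical(prof, prof2)
})
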