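#' Random train/test split of a dataset's molecules
#'
#' Uniform, unstratified hold-out split; `round(test_fraction * n)`
#' molecules go to the test set.
#'
#' @param dataset a `chef_dataset` (or character vector of molecule ids).
#' @param test_fraction held-out fraction in (0, 1) (default 0.1).
#' @param seed RNG seed.
#' @return a `split_spec`: `train`, `test`, `test_fraction`, `seed`.
#' @export
split_dataset <- function(dataset, test_fraction = 0.1, seed = 1L) {
  ids <- if (inherits(dataset, "chef_dataset")) dataset$molecule_ids else dataset
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must lie in (0, 1)", call. = FALSE)
  }
  n_test <- round(test_fraction * length(ids))
  test <- with_seed(seed, sample(ids, n_test))
  structure(list(
    train = setdiff(ids, test),
    test = test,
    test_fraction = test_fraction,
    seed = as.integer(seed)
  ), class = "split_spec")
}

#' Model configuration for the multi-label classifiers
#'
#' Families and default hyperparameters: logistic regression with L2
#' inverse-regularization `C = 0.001` and at most 1000 iterations; random
#' forest with 100 trees of depth at most 10; feedforward network with
#' hidden sizes (512, 256), dropout 0.2, minibatch 32, learning rate 0.001,
#' 5 epochs, binary cross-entropy objective. Hyperparameters are recorded
#' in every artifact the model writes.
#'
#' @param family `"logistic"`, `"random_forest"` or `"feedforward"`.
#' @param ... overrides of the family's hyperparameters.
#' @param seed RNG seed used for training.
#' @return a `model_config`.
#' @export
model_config <- function(family = c("logistic", "random_forest", "feedforward"),
                         ..., seed = 1L) {
  family <- match.arg(family)
  defaults <- switch(family,
    logistic = list(C = 0.001, max_iter = 1000L),
    random_forest = list(n_trees = 100L, max_depth = 10L),
    feedforward = list(hidden = c(512L, 256L), dropout = 0.2,
                       batch_size = 32L, learning_rate = 0.001, epochs = 5L)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown hyperparameter(s) for family '%s': %s",
                 family, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  defaults[names(overrides)] <- overrides
  structure(c(list(family = family, seed = as.integer(seed)), defaults),
            class = "model_config")
}

#' Train a multi-label structure-to-function model
#'
#' Logistic and random-forest families are one-vs-rest: one binary model
#' per label; the feedforward family is a single multi-output network with
#' per-label sigmoids. Labels lacking both a positive and a negative
#' example in the training set are masked (skipped, recorded) rather than
#' failing the run. Only training-split rows ever reach the fitting code.
#'
#' @param config a [model_config()].
#' @param fingerprints a [fingerprint_matrix()] covering all molecules.
#' @param dataset a `chef_dataset` providing the label incidence.
#' @param split a `split_spec` from [split_dataset()].
#' @return a `chef_model`: fitted parameters, `masked_labels`, `config`,
#'   `fingerprint_spec`, `split_seed`, `labels` (unmasked vocabulary).
#' @export
train_multilabel <- function(config, fingerprints, dataset, split) {
  stopifnot(inherits(config, "model_config"), inherits(split, "split_spec"),
            inherits(dataset, "chef_dataset"))
  x <- fingerprints$matrix[split$train, , drop = FALSE]
  y <- as.matrix(dataset$incidence[split$train, , drop = FALSE])
  pos <- colSums(y)
  trainable <- pos >= 1 & pos <= nrow(y) - 1
  masked <- dataset$labels[!trainable]
  labels <- dataset$labels[trainable]
  if (length(labels) == 0L) {
    stop("all labels are masked: none has both classes in the training set",
         call. = FALSE)
  }
  y <- y[, trainable, drop = FALSE]

  fit <- switch(config$family,
    logistic = {
      lambda_target <- 1 / (nrow(x) * config$C)
      coefs <- matrix(0, nrow = ncol(x) + 1L, ncol = length(labels))
      for (j in seq_along(labels)) {
        f <- glmnet::glmnet(x, y[, j], family = "binomial", alpha = 0,
                            lambda = lambda_target,
                            standardize = FALSE, maxit = config$max_iter)
        coefs[, j] <- as.numeric(stats::coef(f, s = lambda_target))
      }
      dimnames(coefs) <- list(c("(Intercept)", colnames(x) %||%
                                  paste0("bit", seq_len(ncol(x)))), labels)
      list(type = "coef", coefs = coefs)
    },
    random_forest = {
      models <- vector("list", length(labels))
      for (j in seq_along(labels)) {
        df <- data.frame(y = factor(y[, j], levels = c(0, 1)), x)
        models[[j]] <- ranger::ranger(
          y ~ ., data = df, num.trees = config$n_trees,
          max.depth = config$max_depth, probability = TRUE,
          seed = child_seed(config$seed, j), num.threads = 1L
        )
      }
      names(models) <- labels
      list(type = "ranger", models = models)
    },
    feedforward = {
      net <- mlp_train(x, y, hidden = config$hidden, dropout = config$dropout,
                       batch_size = config$batch_size,
                       lr = config$learning_rate, epochs = config$epochs,
                       seed = config$seed)
      list(type = "mlp", net = net)
    }
  )
  structure(list(
    fit = fit,
    labels = labels,
    masked_labels = masked,
    config = config,
    fingerprint_spec = fingerprints$spec,
    split_seed = split$seed
  ), class = "chef_model")
}

#' @export
print.chef_model <- function(x, ...) {
  cat(sprintf("<chef_model> %s: %d labels (%d masked), fingerprints %s\n",
              x$config$family, length(x$labels), length(x$masked_labels),
              x$fingerprint_spec$type %||% "?"))
  invisible(x)
}

#' Predict per-molecule functional profiles
#'
#' Probability of every unmasked label for every fingerprinted molecule.
#' The fingerprint spec must match the one the model was trained on.
#'
#' @param model a `chef_model`.
#' @param fingerprints a [fingerprint_matrix()].
#' @return a `prediction_matrix`: numeric matrix (molecules x unmasked
#'   labels) of probabilities, with the model config attached.
#' @export
predict_profiles <- function(model, fingerprints) {
  stopifnot(inherits(model, "chef_model"))
  spec_trained <- model$fingerprint_spec
  spec_new <- fingerprints$spec
  if (!identical(spec_trained$type, spec_new$type) ||
      !identical(spec_trained$n_bits, spec_new$n_bits)) {
    stop(sprintf("fingerprint spec mismatch: model trained on %s/%s bits, got %s/%s bits",
                 spec_trained$type, spec_trained$n_bits,
                 spec_new$type, spec_new$n_bits), call. = FALSE)
  }
  x <- fingerprints$matrix
  probs <- switch(model$fit$type,
    coef = {
      eta <- cbind(1, x) %*% model$fit$coefs
      stats::plogis(eta)
    },
    ranger = {
      out <- matrix(NA_real_, nrow = nrow(x), ncol = length(model$labels))
      df <- data.frame(x)
      for (j in seq_along(model$labels)) {
        pr <- stats::predict(model$fit$models[[j]], data = df,
                             num.threads = 1L)$predictions
        out[, j] <- pr[, "1"]
      }
      out
    },
    mlp = mlp_predict(model$fit$net, x)
  )
  probs <- as.matrix(probs)
  dimnames(probs) <- list(rownames(x), model$labels)
  structure(probs, class = c("prediction_matrix", class(probs)),
            config = model$config, masked_labels = model$masked_labels)
}

#' Evaluate predictions on the held-out test set
#'
#' Per-label ROC-AUC and PR-AUC on the test molecules; labels with no test
#' positives or no test negatives are marked undefined and excluded from
#' the macro averages (their count is reported). Also reports the counts of
#' labels with positive predictive power (ROC-AUC > 0.5) and with
#' ROC-AUC > 0.9.
#'
#' @param predictions a `prediction_matrix` covering the test molecules.
#' @param dataset a `chef_dataset` with the ground-truth incidence.
#' @param split the `split_spec` used in training.
#' @return a `metrics_report`: `per_label` data.frame, `macro_roc_auc`,
#'   `macro_pr_auc`, `n_undefined`, `n_auc_gt_05`, `n_auc_gt_09`.
#' @export
evaluate <- function(predictions, dataset, split) {
  stopifnot(inherits(split, "split_spec"), inherits(dataset, "chef_dataset"))
  test_ids <- intersect(split$test, rownames(predictions))
  labels <- colnames(predictions)
  truth <- as.matrix(dataset$incidence[test_ids, labels, drop = FALSE])
  scores <- predictions[test_ids, , drop = FALSE]
  per_label <- data.frame(
    label = labels,
    n_test_pos = colSums(truth),
    roc_auc = vapply(seq_along(labels),
                     function(j) roc_auc(scores[, j], truth[, j]), numeric(1)),
    pr_auc = vapply(seq_along(labels),
                    function(j) pr_auc(scores[, j], truth[, j]), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(per_label) <- NULL
  defined <- !is.na(per_label$roc_auc)
  structure(list(
    per_label = per_label,
    macro_roc_auc = mean(per_label$roc_auc[defined]),
    macro_pr_auc = mean(per_label$pr_auc[defined & !is.na(per_label$pr_auc)]),
    n_undefined = sum(!defined),
    n_auc_gt_05 = sum(per_label$roc_auc[defined] > 0.5),
    n_auc_gt_09 = sum(per_label$roc_auc[defined] > 0.9),
    n_test = length(test_ids)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> %d test molecules; macro ROC-AUC %.3f, macro PR-AUC %.3f (%d labels undefined)\n",
    x$n_test, x$macro_roc_auc, x$macro_pr_auc, x$n_undefined))
  cat(sprintf("  labels with ROC-AUC > 0.5: %d; > 0.9: %d\n",
              x$n_auc_gt_05, x$n_auc_gt_09))
  invisible(x)
}

#' Ranked label-guided molecule retrieval
#'
#' The top-k molecules by predicted probability for a label, over a chosen
#' molecule subset (typically the held-out test set). Ties are broken by
#' molecule id for determinism.
#'
#' @param predictions a `prediction_matrix`.
#' @param label an unmasked label.
#' @param k number of molecules to return (default 10; the whole subset if
#'   smaller).
#' @param subset molecule ids to rank (default: all predicted molecules).
#' @return data.frame (`rank`, `molecule_id`, `score`).
#' @export
query_top_molecules <- function(predictions, label, k = 10L, subset = NULL) {
  labels <- colnames(predictions)
  if (!label %in% labels) {
    masked <- attr(predictions, "masked_labels") %||% character(0)
    near <- utils::head(c(
      intersect(label, masked),
      labels[utils::adist(label, labels) <= 2]
    ), 5L)
    stop(sprintf("label '%s' is not scored%s%s",
                 label,
                 if (label %in% masked) " (masked during training)" else "",
                 if (length(near) > 0L)
                   paste0("; nearest vocabulary matches: ",
                          paste(near, collapse = ", ")) else ""),
         call. = FALSE)
  }
  ids <- subset %||% rownames(predictions)
  ids <- intersect(ids, rownames(predictions))
  s <- predictions[ids, label]
  ord <- order(-s, ids)
  top <- utils::head(ord, k)
  data.frame(rank = seq_along(top), molecule_id = ids[top],
             score = unname(s[top]), stringsAsFactors = FALSE)
}

#' Annotate molecules with a sorted functional profile
#'
#' Fingerprints the given SMILES with the model's own fingerprint spec and
#' returns, per molecule, the full predicted profile sorted by probability
#' descending — the mechanism-inference use case (e.g. high 'antiviral' and
#' 'hcv' with low 'protease' pointing away from a protease target). A
#' character vector of SMILES serves the repurposing-style scan over a drug
#' list.
#'
#' @param model a `chef_model` trained on chemistry-derived fingerprints.
#' @param smiles character vector of valid SMILES (names become molecule
#'   ids).
#' @return for one SMILES, a data.frame (`label`, `score`) sorted by score;
#'   for several, a named list of such data.frames.
#' @export
annotate_molecule <- function(model, smiles) {
  stopifnot(inherits(model, "chef_model"))
  type <- model$fingerprint_spec$type %||% ""
  if (!startsWith(type, "openbabel-")) {
    stop("model was trained on direct bit-vector fingerprints; supply a fingerprint_matrix to predict_profiles() instead",
         call. = FALSE)
  }
  fp <- compute_fingerprints(smiles, type = sub("openbabel-", "", type))
  probs <- predict_profiles(model, fp)
  profiles <- lapply(seq_len(nrow(probs)), function(i) {
    s <- probs[i, ]
    ord <- order(-s, names(s))
    data.frame(label = names(s)[ord], score = unname(s[ord]),
               stringsAsFactors = FALSE)
  })
  names(profiles) <- rownames(probs)
  if (length(profiles) == 1L) profiles[[1L]] else profiles
}
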