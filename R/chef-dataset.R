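#' Sparse molecule-by-label incidence dataset
#'
#' The central container of the pipeline: a binary sparse incidence matrix
#' over molecules and a functional-label vocabulary, with a label-abundance
#' index (number of molecules carrying each label) kept consistent with the
#' incidence.
#'
#' @param pairs data.frame (`molecule_id`, `label`) of incidence pairs.
#' @param molecule_ids full molecule universe; defaults to the molecules in
#'   `pairs`, but passing the universe explicitly retains molecules whose
#'   label sets are empty.
#' @param labels optional fixed vocabulary; defaults to labels in `pairs`.
#' @return a `chef_dataset`.
#' @export
chef_dataset <- function(pairs, molecule_ids = NULL, labels = NULL) {
  stopifnot(all(c("molecule_id", "label") %in% names(pairs)))
  pairs <- unique(pairs[, c("molecule_id", "label")])
  molecule_ids <- molecule_ids %||% sort(unique(pairs$molecule_id))
  labels <- labels %||% sort(unique(pairs$label))
  if (!all(pairs$molecule_id %in% molecule_ids)) {
    stop("incidence pairs reference molecules outside the given universe", call. = FALSE)
  }
  if (!all(pairs$label %in% labels)) {
    stop("incidence pairs reference labels outside the given vocabulary", call. = FALSE)
  }
  inc <- Matrix::sparseMatrix(
    i = match(pairs$molecule_id, molecule_ids),
    j = match(pairs$label, labels),
    x = 1,
    dims = c(length(molecule_ids), length(labels)),
    dimnames = list(molecule_ids, labels)
  )
  inc@x[] <- 1  # collapse any duplicate entries to binary
  structure(list(
    molecule_ids = molecule_ids,
    labels = labels,
    incidence = inc,
    abundance = stats::setNames(Matrix::colSums(inc), labels)
  ), class = "chef_dataset")
}

#' @export
print.chef_dataset <- function(x, ...) {
  cat(sprintf("<chef_dataset> %d molecules x %d labels, %d incidence pairs\n",
              length(x$molecule_ids), length(x$labels),
              as.integer(sum(x$incidence))))
  invisible(x)
}

#' @export
dim.chef_dataset <- function(x) c(length(x$molecule_ids), length(x$labels))

#' Molecules carrying a label
#' @param dataset a `chef_dataset`.
#' @param label a label in the vocabulary.
#' @return character vector of molecule ids.
#' @export
label_molecules <- function(dataset, label) {
  stopifnot(inherits(dataset, "chef_dataset"))
  if (!label %in% dataset$labels) {
    stop(sprintf("label '%s' is not in the vocabulary", label), call. = FALSE)
  }
  dataset$molecule_ids[dataset$incidence[, label] > 0]
}

#' Label sets per molecule
#' @param dataset a `chef_dataset`.
#' @return named list: molecule id -> character vector of labels.
#' @export
molecule_labels <- function(dataset) {
  stopifnot(inherits(dataset, "chef_dataset"))
  tm <- Matrix::t(dataset$incidence)
  apply_sets <- split(dataset$labels[tm@i + 1L],
                      rep(seq_along(dataset$molecule_ids), diff(tm@p)))
  out <- stats::setNames(vector("list", length(dataset$molecule_ids)),
                         dataset$molecule_ids)
  out[as.integer(names(apply_sets))] <- apply_sets
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  out
}

#' Long-format incidence pairs of a dataset
#' @param dataset a `chef_dataset`.
#' @return data.frame (`molecule_id`, `label`).
#' @export
dataset_pairs <- function(dataset) {
  stopifnot(inherits(dataset, "chef_dataset"))
  sm <- methods::as(dataset$incidence, "TsparseMatrix")
  out <- data.frame(molecule_id = dataset$molecule_ids[sm@i + 1L],
                    label = dataset$labels[sm@j + 1L],
                    stringsAsFactors = FALSE)
  out[order(out$molecule_id, out$label), , drop = FALSE]
}

#' Write a dataset as chef_dataset.csv plus a JSON metadata sidecar
#' @param dataset a `chef_dataset`.
#' @param dir output directory.
#' @param meta extra provenance fields for the sidecar.
#' @return invisibly, the paths written.
#' @export
write_chef_dataset <- function(dataset, dir, meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "chef_dataset.csv")
  pairs <- dataset_pairs(dataset)
  utils::write.csv(pairs, csv, row.names = FALSE)
  sidecar <- file.path(dir, "chef_dataset.json")
  jsonlite::write_json(c(list(
    n_molecules = length(dataset$molecule_ids),
    n_labels = length(dataset$labels),
    abundance = as.list(dataset$abundance)
  ), meta), sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv = csv, sidecar = sidecar))
}

#' Read a chef_dataset.csv written by [write_chef_dataset()]
#' @param path path to the csv.
#' @param molecule_ids optional molecule universe.
#' @return a `chef_dataset`.
#' @export
read_chef_dataset <- function(path, molecule_ids = NULL) {
  chef_dataset(utils::read.csv(path, colClasses = "character"),
               molecule_ids = molecule_ids)
}
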