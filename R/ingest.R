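#' Canonicalize SMILES strings into molecule records
#'
#' Valid strings are replaced by their stereochemistry-preserving canonical
#' form (OpenBabel canonical SMILES via ChemmineOB); malformed strings are
#' dropped and counted; records whose canonical forms coincide are merged
#' with the union of their patent ids.
#'
#' @param molecules either a character vector of SMILES or a data.frame with
#'   columns `molecule_id`, `smiles` and optionally `patent_ids`
#'   (semicolon-joined string).
#' @return data.frame of molecule records (`molecule_id`, `smiles`,
#'   `patent_ids`) with attributes `n_dropped` (malformed strings) and
#'   `n_merged` (duplicate canonical forms collapsed).
#' @export
canonicalize_molecules <- function(molecules) {
  if (is.character(molecules) && length(molecules) == 0L) {
    out <- data.frame(molecule_id = character(0), smiles = character(0),
                      patent_ids = character(0), stringsAsFactors = FALSE)
    attr(out, "n_dropped") <- 0L
    attr(out, "n_merged") <- 0L
    return(out)
  }
  if (is.character(molecules)) {
    molecules <- data.frame(
      molecule_id = if (is.null(names(molecules))) sprintf("mol%05d", seq_along(molecules)) else names(molecules),
      smiles = unname(molecules),
      patent_ids = "",
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("molecule_id", "smiles") %in% names(molecules)))
  if (is.null(molecules$patent_ids)) molecules$patent_ids <- ""
  if (nrow(molecules) == 0L) {
    out <- molecules[0, c("molecule_id", "smiles", "patent_ids")]
    attr(out, "n_dropped") <- 0L
    attr(out, "n_merged") <- 0L
    return(out)
  }
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("ChemmineOB is required for SMILES canonicalization", call. = FALSE)
  }
  canon <- canonical_smiles(molecules$smiles)
  keep <- !is.na(canon)
  n_dropped <- sum(!keep)
  recs <- molecules[keep, , drop = FALSE]
  recs$smiles <- canon[keep]

  # merge duplicate canonical forms, unioning patent ids
  groups <- split(seq_len(nrow(recs)), recs$smiles)
  merged <- lapply(groups, function(idx) {
    idx <- sort(idx)
    pats <- unique(unlist(strsplit(recs$patent_ids[idx], ";", fixed = TRUE)))
    pats <- pats[nzchar(pats)]
    data.frame(
      molecule_id = recs$molecule_id[idx[1L]],
      smiles = recs$smiles[idx[1L]],
      patent_ids = paste(pats, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, merged)
  out <- out[order(match(out$molecule_id, molecules$molecule_id)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_merged") <- nrow(recs) - nrow(out)
  out
}

# Canonical SMILES for a vector of strings; NA where the string does not
# parse. Conversion runs one molecule at a time because the OpenBabel batch
# converter stops at the first malformed entry.
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))),
      error = function(e) ""
    )
    can <- strsplit(out, "[ \t\n]+")[[1]]
    if (length(can) >= 1L && nzchar(can[[1L]])) can[[1L]] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

patent_count <- function(patent_ids) {
  vapply(strsplit(patent_ids, ";", fixed = TRUE),
         function(p) sum(nzchar(p)), integer(1))
}

#' Filter molecule records by patent count
#'
#' Keeps records associated with fewer than `max_exclusive` patents. Heavily
#' patented molecules (penicillin-class compounds can carry tens of
#' thousands of patents) dilute functional labels, so the corpus restricts
#' to molecules whose patents are likely about them.
#'
#' @param records molecule record data.frame with a `patent_ids` column
#'   (semicolon-joined).
#' @param max_exclusive exclusive upper bound on patent count (default 10:
#'   a molecule with 9 patents is kept, one with 10 is dropped).
#' @return the kept records, with attributes `n_kept` and `n_dropped`.
#' @export
filter_by_patent_count <- function(records, max_exclusive = 10L) {
  counts <- patent_count(records$patent_ids)
  keep <- counts < max_exclusive
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

squish <- function(x) gsub("[[:space:]]+", " ", trimws(x %||% ""))

#' Assemble the text submitted to an extraction backend
#'
#' Concatenates a patent's title, abstract, and the first `desc_chars`
#' characters of its description (after whitespace normalization), under
#' explicit section markers. Truncation is a plain character cut and may
#' split a word.
#'
#' @param doc a list or one-row data.frame with `title`, `abstract`,
#'   `description`.
#' @param desc_chars description truncation length (default 3500 characters).
#' @return a single string.
#' @export
make_extraction_input <- function(doc, desc_chars = 3500L) {
  desc <- squish(doc$description)
  desc <- substr(desc, 1L, desc_chars)
  paste0(
    "TITLE: ", squish(doc$title), "\n",
    "ABSTRACT: ", squish(doc$abstract), "\n",
    "DESCRIPTION: ", desc
  )
}

#' Construct a label-extraction backend
#'
#' A backend maps truncated patent text to a handful of short functional
#' labels. The package ships a deterministic dictionary backend
#' ([mock_extraction_backend()]) used for all testing; an adapter for a live
#' LLM API can be plugged in through the same interface.
#'
#' @param name backend name (recorded in outputs).
#' @param extract function(text) -> character vector of labels.
#' @return an `extraction_backend`.
#' @export
extraction_backend <- function(name, extract) {
  stopifnot(is.character(name), is.function(extract))
  structure(list(name = name, extract = extract), class = "extraction_backend")
}

#' Dictionary keyword-spotting extraction backend
#'
#' Deterministic stand-in for an LLM summarizer: scans the truncated patent
#' text for whole-word occurrences of dictionary terms and returns the
#' matches in order of first occurrence. On corpora whose documents embed
#' their molecules' label keywords, this recovers the planted labels
#' exactly.
#'
#' @param dictionary character vector of candidate labels to spot.
#' @return an `extraction_backend`.
#' @export
mock_extraction_backend <- function(dictionary) {
  dictionary <- unique(dictionary)
  extraction_backend("mock", function(text) {
    text <- tolower(text)
    pos <- vapply(dictionary, function(w) {
      m <- regexpr(paste0("\\b", w, "\\b"), text, perl = TRUE)
      as.integer(m[1])
    }, integer(1))
    hits <- dictionary[pos > 0L]
    hits[order(pos[pos > 0L])]
  })
}

#' Extract raw functional labels from patent documents
#'
#' Runs an extraction backend over each (molecule, patent) document,
#' clipping backend output to at most 3 labels (first three, with a
#' warning) and recording empty output as a per-document extraction failure
#' rather than an error.
#'
#' @param backend an [extraction_backend()].
#' @param docs data.frame of patent documents (`patent_id`, `molecule_id`,
#'   `title`, `abstract`, `description`).
#' @param desc_chars description truncation passed to
#'   [make_extraction_input()].
#' @param max_labels per-document label cap (default 3).
#' @return data.frame (`molecule_id`, `patent_id`, `raw_label`) with
#'   attribute `failures` listing documents yielding no labels.
#' @export
extract_labels <- function(backend, docs, desc_chars = 3500L, max_labels = 3L) {
  stopifnot(inherits(backend, "extraction_backend"))
  rows <- vector("list", nrow(docs))
  failures <- character(0)
  n_clipped <- 0L
  for (i in seq_len(nrow(docs))) {
    doc <- docs[i, , drop = FALSE]
    labs <- backend$extract(make_extraction_input(doc, desc_chars))
    if (length(labs) > max_labels) {
      n_clipped <- n_clipped + 1L
      labs <- labs[seq_len(max_labels)]
    }
    if (length(labs) == 0L) {
      failures <- c(failures, doc$patent_id)
      next
    }
    rows[[i]] <- data.frame(molecule_id = doc$molecule_id,
                            patent_id = doc$patent_id,
                            raw_label = labs, stringsAsFactors = FALSE)
  }
  if (n_clipped > 0L) {
    warning(sprintf("backend returned more than %d labels for %d document(s); clipped to the first %d",
                    max_labels, n_clipped, max_labels), call. = FALSE)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(molecule_id = character(0), patent_id = character(0),
               raw_label = character(0))
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

# Plurals that must not lose a final "s"; tokens ending in ss/us/is are
# protected by rule.
protected_singulars <- function() {
  c("diabetes", "rabies", "series", "species", "herpes", "measles",
    "mumps", "news", "aids", "caries")
}

singularize <- function(tokens) {
  protect <- tokens %in% protected_singulars() |
    grepl("(ss|us|is)$", tokens) | nchar(tokens) <= 2L
  drop_s <- grepl("s$", tokens) & !protect
  tokens[drop_s] <- sub("s$", "", tokens[drop_s])
  tokens
}

clean_label_tokens <- function(raw) {
  tokens <- unlist(strsplit(squish(tolower(raw)), " ", fixed = TRUE))
  # strip punctuation at token edges; internal hyphens/alphanumerics kept
  tokens <- gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", tokens)
  tokens <- tokens[nzchar(tokens)]
  unique(singularize(tokens))
}

#' Clean raw extracted labels into word-level label rows
#'
#' Each raw label is whitespace-split into tokens, lowercased, stripped of
#' edge punctuation (internal hyphens such as in "5-ht" survive), and
#' singularized by rule (final "s" dropped unless the token ends in "ss",
#' "us", "is" or is a protected irregular). Labels from all of a molecule's
#' patents are unioned and deduplicated, so the output is per molecule.
#' The operation is idempotent.
#'
#' @param raw_labels data.frame (`molecule_id`, `raw_label`) as produced by
#'   [extract_labels()], or a character vector (cleaned tokens returned
#'   directly).
#' @return data.frame (`molecule_id`, `label`), one row per molecule-label.
#' @export
clean_labels <- function(raw_labels) {
  if (is.character(raw_labels)) {
    return(unique(unlist(lapply(raw_labels, clean_label_tokens))))
  }
  stopifnot(all(c("molecule_id", "raw_label") %in% names(raw_labels)))
  per_mol <- split(raw_labels$raw_label, raw_labels$molecule_id)
  rows <- lapply(names(per_mol), function(m) {
    toks <- unique(unlist(lapply(per_mol[[m]], clean_label_tokens)))
    if (length(toks) == 0L) return(NULL)
    data.frame(molecule_id = m, label = toks, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(molecule_id = character(0), label = character(0))
  rownames(out) <- NULL
  out
}

#' Read a molecules.csv file
#' @param path file path (columns `molecule_id`, `smiles`, `patent_ids`).
#' @return data.frame of molecule records.
#' @export
read_molecules_csv <- function(path) {
  utils::read.csv(path, colClasses = "character")
}

#' Read a patents.jsonl file (one JSON document per line)
#' @param path file path.
#' @return data.frame (`patent_id`, `molecule_id`, `title`, `abstract`,
#'   `description`).
#' @export
read_patents_jsonl <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(ln) {
    as.data.frame(jsonlite::fromJSON(ln), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
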