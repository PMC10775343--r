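#' Configuration for the synthetic patent-chemistry corpus
#'
#' The generator emulates the statistical structure the downstream analyses
#' assume: molecule populations organised into structural scaffolds whose
#' members are highly similar in fingerprint space, functional labels
#' concentrated on scaffolds with tunable reassignment noise, independent
#' per-molecule background labels with no structural signal, and
#' pseudo-patent documents whose text contains each molecule's label
#' keywords so that a dictionary extraction backend can recover them.
#'
#' Defaults define the standing desk-scale study conditions used by the
#' package's own analyses and tests: 10 scaffolds of 100 molecules on
#' 2048-bit fingerprints, 2% per-bit mutation, 20 planted labels (two per
#' scaffold), 20 structure-free background labels at 5% incidence, and 2%
#' label-reassignment noise (the realistic rate of labels that do not
#' describe their own molecule in patent-derived corpora).
#'
#' @param n_scaffolds number of scaffolds (structural families).
#' @param members_per_scaffold molecules per scaffold.
#' @param n_bits fingerprint length for the direct bit-vector track.
#' @param prototype_density fraction of bits set in each scaffold prototype.
#' @param flip_rate per-bit mutation probability when deriving a member from
#'   its scaffold prototype; must be < 0.5 or the scaffold signal vanishes.
#' @param n_planted_labels number of scaffold-linked functional labels.
#' @param labels_per_scaffold planted labels attached to each scaffold.
#' @param n_background_labels number of structure-free background labels.
#' @param background_rate per-molecule probability of each background label.
#' @param label_noise probability that a planted label attachment is
#'   reassigned to a uniformly random molecule.
#' @param patents_per_molecule pseudo-patents generated per molecule (< 10 so
#'   generated corpora pass the patent-count filter).
#' @param seed RNG seed; identical config + seed gives a byte-identical corpus.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_scaffolds = 10,
                             members_per_scaffold = 100,
                             n_bits = 2048,
                             prototype_density = 0.05,
                             flip_rate = 0.02,
                             n_planted_labels = 20,
                             labels_per_scaffold = 2,
                             n_background_labels = 20,
                             background_rate = 0.05,
                             label_noise = 0.02,
                             patents_per_molecule = 3,
                             seed = 1L) {
  cfg <- list(
    n_scaffolds = stop_if_not_count(n_scaffolds, "n_scaffolds"),
    members_per_scaffold = stop_if_not_count(members_per_scaffold, "members_per_scaffold"),
    n_bits = stop_if_not_count(n_bits, "n_bits"),
    prototype_density = prototype_density,
    flip_rate = flip_rate,
    n_planted_labels = stop_if_not_count(n_planted_labels, "n_planted_labels"),
    labels_per_scaffold = stop_if_not_count(labels_per_scaffold, "labels_per_scaffold"),
    n_background_labels = stop_if_not_count(n_background_labels, "n_background_labels", min = 0L),
    background_rate = background_rate,
    label_noise = label_noise,
    patents_per_molecule = stop_if_not_count(patents_per_molecule, "patents_per_molecule"),
    seed = as.integer(seed)
  )
  if (!is.numeric(prototype_density) || prototype_density <= 0 || prototype_density >= 1) {
    stop("`prototype_density` must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(flip_rate) || flip_rate < 0 || flip_rate >= 0.5) {
    stop("`flip_rate` must lie in [0, 0.5): at 0.5 the scaffold signal vanishes",
         call. = FALSE)
  }
  stop_if_not_prob(background_rate, "background_rate")
  stop_if_not_prob(label_noise, "label_noise")
  if (cfg$patents_per_molecule >= 10L) {
    stop("`patents_per_molecule` must be < 10 so synthetic molecules pass the patent-count filter",
         call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# Pool of clean, single-token functional words. All survive label cleaning
# unchanged (lower case, singular, no edge punctuation); numbered variants
# are appended when more names are requested than the pool holds.
functional_word_pool <- function() {
  c(
    "antiviral", "antibacterial", "antifungal", "kinase", "protease",
    "polymerase", "inhibitor", "agonist", "antagonist", "analgesic",
    "anesthetic", "antidepressant", "antihistamine", "anticoagulant",
    "antioxidant", "vasodilator", "diuretic", "sedative", "herbicide",
    "fungicide", "insecticide", "electroluminescent", "photoinitiator",
    "surfactant", "catalyst", "adhesive", "polymer", "semiconductor",
    "antitumor", "antiproliferative", "immunosuppressant", "bronchodilator",
    "antipsychotic", "anticonvulsant", "antimalarial", "antihypertensive",
    "hypoglycemic", "neuroprotective", "antiemetic", "antiseptic",
    "antithrombotic", "anxiolytic", "hepatoprotective", "antiparasitic"
  )
}

functional_label_names <- function(n) {
  pool <- functional_word_pool()
  if (n <= length(pool)) return(pool[seq_len(n)])
  extra <- n - length(pool)
  c(pool, paste0(rep(pool, length.out = extra), rep(seq_len(ceiling(extra / length(pool))) + 1L,
                                                    each = length(pool))[seq_len(extra)]))
}

molecule_ids <- function(n) sprintf("mol%05d", seq_len(n))

#' Generate a scaffold-structured fingerprint population
#'
#' Draws one prototype bit vector per scaffold — `round(prototype_density *
#' n_bits)` bits set, at positions sampled independently per scaffold — then
#' derives each member by flipping every prototype bit independently with
#' probability `flip_rate`. Prototypes carry exactly the same number of set
#' bits so scaffolds are structurally exchangeable: differences between
#' labels reflect their molecular membership, not nuisance variation in
#' scaffold complexity. At `flip_rate = 0` all members of a scaffold are
#' identical; as it grows, within-scaffold Tanimoto similarity decays
#' towards the background level.
#'
#' @param config a [synthetic_config()].
#' @return list with `fingerprints` (a [fingerprint_matrix()]) and
#'   `scaffold_of` (named integer vector, molecule id -> scaffold index).
#' @export
generate_fingerprint_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n_mol <- config$n_scaffolds * config$members_per_scaffold
  ids <- molecule_ids(n_mol)
  with_seed(child_seed(config$seed, 1L), {
    n_set <- max(1L, round(config$prototype_density * config$n_bits))
    protos <- t(vapply(seq_len(config$n_scaffolds), function(s) {
      v <- integer(config$n_bits)
      v[sample.int(config$n_bits, n_set)] <- 1L
      v
    }, integer(config$n_bits)))
    scaffold_of <- rep(seq_len(config$n_scaffolds), each = config$members_per_scaffold)
    flips <- matrix(rbinom(n_mol * config$n_bits, 1L, config$flip_rate), nrow = n_mol)
    mat <- abs(protos[scaffold_of, , drop = FALSE] - flips)  # XOR on 0/1
    rownames(mat) <- ids
    names(scaffold_of) <- ids
    list(
      fingerprints = fingerprint_matrix(mat, spec = list(
        type = "synthetic-scaffold-bits", n_bits = config$n_bits,
        prototype_density = config$prototype_density, flip_rate = config$flip_rate
      )),
      scaffold_of = scaffold_of,
      prototypes = protos
    )
  })
}

#' Scaffold template library for the SMILES generation track
#'
#' Each template carries one substitution slot written `([*])`; removing the
#' slot gives the bare scaffold, filling it gives a decorated member.
#'
#' @return character vector of templates with slots.
#' @export
scaffold_templates <- function() {
  c(
    "c1ccc([*])cc1",              # benzene
    "C1CCC([*])CC1",              # cyclohexane
    "c1ccnc([*])c1",              # pyridine
    "C1CCN([*])CC1",              # piperidine
    "c1ccc2cc([*])ccc2c1",        # naphthalene
    "c1ccc(O[*])cc1",             # aryl ether
    "C1CN([*])CCO1",              # morpholine
    "c1ccc(N([*])C)cc1",          # N-methylaniline
    "c1csc([*])c1",               # thiophene
    "c1ccc(C(=O)N[*])cc1",        # benzamide
    "C1CCC(C([*])=O)CC1",         # cyclohexyl ketone
    "c1cnc2[nH]ccc2c1[*]"         # azaindole
  )
}

substituent_library <- function() {
  c("C", "CC", "CCC", "CC(C)C", "CCO", "OC", "N", "NC", "F", "Cl", "Br",
    "C(=O)C", "C(=O)OC", "C#N", "CF", "CCl")
}

fill_template <- function(template, substituent) {
  if (!grepl("[*]", template, fixed = TRUE)) {
    stop("template has no substitution slot", call. = FALSE)
  }
  if (is.na(substituent) || substituent == "") {
    out <- sub("[*]", "", template, fixed = TRUE)
    # a bare attachment like N([*]) collapses to N(); drop empty parentheses
    gsub("()", "", out, fixed = TRUE)
  } else {
    sub("[*]", substituent, template, fixed = TRUE)
  }
}

#' Generate a scaffold-structured SMILES population
#'
#' Members of each scaffold share a fixed template from a built-in library;
#' decorations are random substituents placed at the template's attachment
#' point, so all members of a scaffold contain the bare template as a common
#' substructure and every emitted string parses as a valid molecule. The
#' first member of each scaffold is always the undecorated template.
#'
#' @param config a [synthetic_config()]; `n_scaffolds` must not exceed the
#'   template library size.
#' @return data.frame with columns `molecule_id`, `smiles`, `scaffold`.
#' @export
generate_smiles_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  templates <- scaffold_templates()
  if (config$n_scaffolds > length(templates)) {
    stop(sprintf("SMILES track supports at most %d scaffolds (template library size)",
                 length(templates)), call. = FALSE)
  }
  subs <- substituent_library()
  n_mol <- config$n_scaffolds * config$members_per_scaffold
  ids <- molecule_ids(n_mol)
  with_seed(child_seed(config$seed, 2L), {
    rows <- vector("list", config$n_scaffolds)
    for (s in seq_len(config$n_scaffolds)) {
      tpl <- templates[[s]]
      smi <- character(config$members_per_scaffold)
      smi[1L] <- fill_template(tpl, "")
      if (config$members_per_scaffold > 1L) {
        chosen <- sample(subs, config$members_per_scaffold - 1L, replace = TRUE)
        smi[-1L] <- vapply(chosen, function(x) fill_template(tpl, x), character(1))
      }
      rows[[s]] <- data.frame(
        scaffold = s, smiles = smi, stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    data.frame(
      molecule_id = ids,
      smiles = out$smiles,
      scaffold = out$scaffold,
      stringsAsFactors = FALSE
    )
  })
}

#' Assign planted and background labels to a molecule population
#'
#' Planted labels are attached to every molecule of their assigned
#' scaffold(s) (labels are dealt to scaffolds in consecutive blocks of
#' `labels_per_scaffold`, cycling if needed); each attachment is then
#' reassigned to a uniformly random molecule with probability `label_noise`.
#' Background labels are attached to each molecule independently with
#' probability `background_rate`, giving a calibrated structure-free
#' negative class.
#'
#' @param scaffold_of named integer vector (molecule id -> scaffold).
#' @param config a [synthetic_config()].
#' @return data.frame (`molecule_id`, `label`) with attributes
#'   `planted_labels` and `background_labels`.
#' @export
assign_labels <- function(scaffold_of, config) {
  stopifnot(inherits(config, "synthetic_config"))
  ids <- names(scaffold_of)
  n_mol <- length(ids)
  all_names <- functional_label_names(config$n_planted_labels + config$n_background_labels)
  planted <- all_names[seq_len(config$n_planted_labels)]
  background <- all_names[config$n_planted_labels + seq_len(config$n_background_labels)]

  with_seed(child_seed(config$seed, 3L), {
    rows <- vector("list", length(planted) + length(background))
    for (j in seq_along(planted)) {
      scaf <- ((j - 1L) %/% config$labels_per_scaffold) %% config$n_scaffolds + 1L
      mols <- ids[scaffold_of == scaf]
      if (config$label_noise > 0 && length(mols) > 0) {
        move <- runif(length(mols)) < config$label_noise
        mols[move] <- sample(ids, sum(move), replace = TRUE)
      }
      rows[[j]] <- data.frame(molecule_id = mols, label = planted[j],
                              stringsAsFactors = FALSE)
    }
    for (b in seq_along(background)) {
      hit <- ids[runif(n_mol) < config$background_rate]
      rows[[length(planted) + b]] <- data.frame(
        molecule_id = hit, label = rep(background[b], length(hit)),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    out <- unique(out)
    rownames(out) <- NULL
    attr(out, "planted_labels") <- planted
    attr(out, "background_labels") <- background
    out
  })
}

filler_word_pool <- function() {
  c("method", "composition", "embodiment", "formulation", "preparation",
    "example", "mixture", "solution", "process", "treatment", "disclosed",
    "invention", "present", "provided", "comprising", "wherein", "suitable",
    "effective", "amount", "administered", "subject", "optionally",
    "derivative", "salt", "carrier", "excipient", "dosage", "tablet",
    "described", "further", "preferred", "aspect", "therein", "thereof")
}

filler_sentence <- function(n_words = 8L) {
  paste0(paste(sample(filler_word_pool(), n_words, replace = TRUE), collapse = " "), ".")
}

label_sentence <- function(keyword) {
  sprintf("The disclosed compound is useful as a %s in the described applications.",
          keyword)
}

#' Generate pseudo-patent documents carrying a corpus's label keywords
#'
#' For each molecule, emits `patents_per_molecule` documents whose abstract
#' and description interleave filler prose with sentences containing every
#' one of the molecule's truth-label keywords. Keyword sentence order is
#' rotated across a molecule's documents so that a backend limited to three
#' labels per document still recovers the full set across documents.
#' Descriptions are padded with filler beyond 3,500 characters — with all
#' keyword sentences guaranteed before that offset — so the truncation step
#' downstream is genuinely exercised.
#'
#' @param truth data.frame (`molecule_id`, `label`) of truth assignments.
#' @param molecule_idv character vector of all molecule ids (molecules with
#'   no labels still get documents).
#' @param config a [synthetic_config()].
#' @param min_description_chars pad descriptions past this length (default 3600).
#' @return data.frame (`patent_id`, `molecule_id`, `title`, `abstract`,
#'   `description`).
#' @export
generate_patent_docs <- function(truth, molecule_idv, config,
                                 min_description_chars = 3600L) {
  stopifnot(inherits(config, "synthetic_config"))
  labels_of <- split(truth$label, factor(truth$molecule_id, levels = molecule_idv))
  with_seed(child_seed(config$seed, 4L), {
    recs <- vector("list", length(molecule_idv) * config$patents_per_molecule)
    k <- 0L
    for (m in molecule_idv) {
      kws <- labels_of[[m]] %||% character(0)
      for (p in seq_len(config$patents_per_molecule)) {
        k <- k + 1L
        rot <- if (length(kws) > 1L) {
          off <- (p - 1L) %% length(kws)
          c(kws[(off + 1L):length(kws)], kws[seq_len(off)])
        } else kws
        title <- sprintf("Compositions relating to compound %s and methods of use", m)
        abstract <- paste(
          filler_sentence(10L),
          if (length(rot)) label_sentence(rot[1L]) else filler_sentence(8L),
          filler_sentence(9L)
        )
        body <- character(0)
        for (kw in rot) {
          body <- c(body, label_sentence(kw), filler_sentence())
        }
        desc <- paste(body, collapse = " ")
        while (nchar(desc) < min_description_chars) {
          desc <- paste(desc, filler_sentence(12L))
        }
        recs[[k]] <- data.frame(
          patent_id = sprintf("PAT-%s-%02d", m, p),
          molecule_id = m, title = title, abstract = abstract,
          description = desc, stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}

#' Generate a complete synthetic corpus
#'
#' Orchestrates the generators into a single corpus object: molecules (with
#' patent id lists and, on the SMILES track, structures), fingerprints (bit
#' track), ground-truth label incidence, scaffold membership, and
#' pseudo-patent documents. Identical config and seed give identical corpora.
#'
#' @param config a [synthetic_config()].
#' @param track `"bits"` (direct fingerprint vectors; default) or `"smiles"`
#'   (template-decorated structures exercising the chemistry code path).
#' @param with_patents generate pseudo-patent text (default TRUE).
#' @return a `synthetic_corpus` list.
#' @export
generate_corpus <- function(config = synthetic_config(),
                            track = c("bits", "smiles"),
                            with_patents = TRUE) {
  track <- match.arg(track)
  if (track == "bits") {
    pop <- generate_fingerprint_population(config)
    scaffold_of <- pop$scaffold_of
    molecules <- data.frame(molecule_id = names(scaffold_of),
                            smiles = NA_character_, stringsAsFactors = FALSE)
    fingerprints <- pop$fingerprints
  } else {
    smi <- generate_smiles_population(config)
    scaffold_of <- stats::setNames(smi$scaffold, smi$molecule_id)
    molecules <- data.frame(molecule_id = smi$molecule_id, smiles = smi$smiles,
                            stringsAsFactors = FALSE)
    fingerprints <- NULL
  }
  truth <- assign_labels(scaffold_of, config)
  patents <- NULL
  if (with_patents) {
    patents <- generate_patent_docs(truth, molecules$molecule_id, config)
    pid_of <- split(patents$patent_id, factor(patents$molecule_id,
                                              levels = molecules$molecule_id))
    molecules$patent_ids <- vapply(pid_of, paste, character(1), collapse = ";")
  } else {
    molecules$patent_ids <- ""
  }
  structure(list(
    molecules = molecules,
    fingerprints = fingerprints,
    truth = truth,
    planted_labels = attr(truth, "planted_labels"),
    background_labels = attr(truth, "background_labels"),
    scaffold_of = scaffold_of,
    patents = patents,
    config = config
  ), class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf(
    "<synthetic_corpus> %d molecules, %d scaffolds, %d truth assignments, %s patent docs\n",
    nrow(x$molecules), x$config$n_scaffolds, nrow(x$truth),
    if (is.null(x$patents)) "no" else as.character(nrow(x$patents))
  ))
  invisible(x)
}

#' Write a synthetic corpus to disk in the pipeline's interchange formats
#'
#' Writes `molecules.csv` (molecule_id, smiles, semicolon-joined patent_ids),
#' `truth_labels.csv`, `patents.jsonl` (one JSON document per line) and, on
#' the bit track, `fingerprints.txt` (space-separated 0/1 matrix preceded by
#' the molecule id on each row).
#'
#' @param corpus a `synthetic_corpus`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    molecules = file.path(dir, "molecules.csv"),
    truth = file.path(dir, "truth_labels.csv")
  )
  utils::write.csv(corpus$molecules, paths["molecules"], row.names = FALSE)
  truth <- corpus$truth
  attr(truth, "planted_labels") <- NULL
  attr(truth, "background_labels") <- NULL
  utils::write.csv(truth, paths["truth"], row.names = FALSE)
  if (!is.null(corpus$patents)) {
    paths["patents"] <- file.path(dir, "patents.jsonl")
    con <- file(paths["patents"], "w")
    on.exit(close(con), add = TRUE)
    for (i in seq_len(nrow(corpus$patents))) {
      writeLines(jsonlite::toJSON(as.list(corpus$patents[i, , drop = FALSE][
        , c("patent_id", "molecule_id", "title", "abstract", "description")]),
        auto_unbox = TRUE), con)
    }
  }
  if (!is.null(corpus$fingerprints)) {
    paths["fingerprints"] <- file.path(dir, "fingerprints.txt")
    m <- corpus$fingerprints$matrix
    lines <- paste(rownames(m), apply(m, 1L, paste, collapse = " "))
    writeLines(lines, paths["fingerprints"])
  }
  invisible(paths)
}

#' Read a plain-text 0/1 fingerprint matrix written by [write_corpus()]
#'
#' @param path file path.
#' @param spec fingerprint spec to attach (default marks it as file-loaded).
#' @return a [fingerprint_matrix()].
#' @export
read_fingerprints_txt <- function(path, spec = list(type = "file")) {
  lines <- readLines(path)
  parts <- strsplit(lines, " ", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  mat <- do.call(rbind, lapply(parts, function(p) as.integer(p[-1L])))
  rownames(mat) <- ids
  fingerprint_matrix(mat, spec)
}
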