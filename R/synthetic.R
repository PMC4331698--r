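# Seeded synthetic CHEMDNER-style corpora with planted chemical-like
# mentions. Entity surface forms are built from the same affix morphology
# the domain-feature family knows (so feature ablations behave
# qualitatively like real data), carrier text is plain English vocabulary
# free of chemical affixes, and a held-out stem list can be switched in to
# probe generalization to unseen chemical cores.

# Carrier vocabulary: common scientific English, screened against the
# chemical prefix/suffix tables so carrier tokens do not fire domain
# features.
CARRIER_WORDS <- c(
  "the", "of", "and", "in", "to", "with", "for", "was", "were", "is", "are",
  "we", "this", "that", "study", "results", "showed", "effect", "effects",
  "on", "after", "exposure", "patients", "cells", "levels", "observed",
  "significant", "increase", "activity", "compared", "group", "groups",
  "using", "analysis", "data", "measured", "samples", "from", "by", "at",
  "higher", "lower", "response", "model", "under", "these", "found",
  "changes", "may", "can", "dose", "doses", "treated", "solution",
  "containing", "added", "between", "role", "both", "more", "than", "when",
  "which", "also", "over", "time", "first", "two", "three", "present",
  "reported", "suggest", "known", "system", "function", "important",
  "specific", "tested", "values", "during")

# Words that preferentially flank planted entities, giving word
# representations a context signal to pick up.
CUE_BEFORE <- c("using", "added", "containing", "treated")
CUE_AFTER <- c("solution", "exposure", "dose", "levels")

SYS_STEMS_TRAIN <- c("ox", "fluor", "chlor", "brom", "iod", "sulf", "carb",
                     "nitr", "phosph", "azin", "thi", "cyan", "sil", "bor",
                     "stann")
SYS_STEMS_HOLDOUT <- c("selen", "tellur", "arsen", "germ", "plumb")
TRIV_STEMS_TRAIN <- c("aspir", "caffe", "morph", "nicot", "atrop", "quinid",
                      "digox", "warfar", "hepar", "resorc", "salbut",
                      "predn", "estrad", "testost", "cortis", "dopam",
                      "serot", "melat", "rifamp", "tetrac")
TRIV_STEMS_HOLDOUT <- c("glibencl", "omepraz", "simvast", "clopid", "metform")
TRIV_SUFFIXES <- c("in", "ine", "ol", "one", "ate")
NOCLASS_TOKENS <- c("solvex", "reagentum", "chemozoid")
SIZE_PREFIXES <- c("meth", "eth", "prop", "but", "pent", "hex", "hept",
                   "oct", "non", "dec")
MULT_PREFIXES <- c("di", "tri", "tetra", "penta", "hexa", "hepta")
LOCANTS <- c("1", "2", "3", "1,2", "1,3", "2,4", "1,2,3")

# Default type mixture: the per-type share of mentions in a real annotated
# training corpus of this kind.
DEFAULT_TYPE_MIXTURE <- c(ABBREVIATION = 4538, FAMILY = 4090, FORMULA = 4448,
                          IDENTIFIER = 672, MULTIPLE = 202, SYSTEMATIC = 6656,
                          TRIVIAL = 8832, NO_CLASS = 40) / 29478

#' Synthetic corpus configuration
#'
#' @param n_documents Number of documents to generate.
#' @param sentences_per_doc Integer range (min, max) of abstract sentences
#'   per document; the title adds one more sentence.
#' @param entity_density Mean planted mentions per sentence.
#' @param type_mixture Named probability vector over the eight entity types.
#' @param n_carrier Number of carrier vocabulary words to use.
#' @param n_stems Number of chemical stems to use (per stem pool).
#' @param use_holdout_stems Draw a share of entity cores from the held-out
#'   stem lists (never used by default, so a corpus generated with this flag
#'   probes generalization to unseen stems).
#' @param seed Integer seed; the same configuration always yields a
#'   byte-identical corpus.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_documents = 100L,
                         sentences_per_doc = c(2L, 4L),
                         entity_density = 1.2,
                         type_mixture = DEFAULT_TYPE_MIXTURE,
                         n_carrier = length(CARRIER_WORDS),
                         n_stems = 15L,
                         use_holdout_stems = FALSE,
                         seed = 42L) {
  stopifnot(n_documents >= 1, length(sentences_per_doc) == 2,
            sentences_per_doc[1] >= 1,
            sentences_per_doc[2] >= sentences_per_doc[1],
            entity_density > 0, n_carrier >= 10, n_stems >= 2)
  type_mixture <- type_mixture[ENTITY_TYPES]
  if (anyNA(type_mixture)) stop("type_mixture must cover all eight entity types")
  if (abs(sum(type_mixture) - 1) > 1e-8) stop("type_mixture must sum to 1")
  structure(list(n_documents = as.integer(n_documents),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 entity_density = entity_density,
                 type_mixture = type_mixture,
                 n_carrier = as.integer(n_carrier),
                 n_stems = as.integer(n_stems),
                 use_holdout_stems = isTRUE(use_holdout_stems),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Stem pools under a config: training stems, plus held-out stems when the
# flag is on (or when `all` is requested, as for unlabeled text).
.stem_pools <- function(config, all = FALSE) {
  sys <- utils::head(SYS_STEMS_TRAIN, config$n_stems)
  triv <- utils::head(TRIV_STEMS_TRAIN, config$n_stems)
  if (all || config$use_holdout_stems) {
    sys <- c(sys, SYS_STEMS_HOLDOUT)
    triv <- c(triv, TRIV_STEMS_HOLDOUT)
  }
  list(sys = sys, triv = triv)
}

# One entity surface string of the given type. Surfaces are always flanked
# by spaces in the sentence, so mention boundaries align with token
# boundaries.
.entity_surface <- function(etype, pools) {
  systematic <- function(locant_ok = TRUE) {
    mult <- if (stats::runif(1) < 0.5) sample(MULT_PREFIXES, 1) else ""
    name <- paste0(mult, sample(SIZE_PREFIXES, 1), sample(pools$sys, 1),
                   sample(CHEM_SUFFIXES, 1))
    if (locant_ok && stats::runif(1) < 0.35) {
      name <- paste0(sample(LOCANTS, 1), "-", name)
    }
    name
  }
  trivial <- function() {
    name <- paste0(sample(pools$triv, 1), sample(TRIV_SUFFIXES, 1))
    if (stats::runif(1) < 0.15) {
      name <- paste0(toupper(substr(name, 1, 1)), substr(name, 2, nchar(name)))
    }
    name
  }
  switch(etype,
    SYSTEMATIC = systematic(),
    TRIVIAL = trivial(),
    FAMILY = paste0(sample(MULT_PREFIXES, 1), sample(SIZE_PREFIXES, 1),
                    sample(pools$sys, 1), sample(CHEM_SUFFIXES, 1), "s"),
    FORMULA = {
      k <- sample(2:4, 1)
      el <- sample(c("C", "H", "O", "N", "S", "P", "Cl", "Na", "Fe", "Zn"), k,
                   replace = TRUE)
      dg <- ifelse(stats::runif(k) < 0.7, sample(1:9, k, replace = TRUE), "")
      paste0(paste0(el, dg), collapse = "")
    },
    ABBREVIATION = paste0(sample(LETTERS, sample(2:5, 1), replace = TRUE),
                          collapse = ""),
    IDENTIFIER = paste0(paste0(sample(LETTERS, sample(2:3, 1), replace = TRUE),
                               collapse = ""),
                        paste0(sample(0:9, sample(3:6, 1), replace = TRUE),
                               collapse = "")),
    MULTIPLE = paste(systematic(locant_ok = FALSE),
                     "and", trivial()),
    NO_CLASS = sample(NOCLASS_TOKENS, 1),
    stop("unknown entity type ", etype))
}

# One sentence: carrier words with entities spliced in. Returns the sentence
# text (ending in ".") and a local mention frame (0-based offsets within the
# sentence).
.make_sentence <- function(config, pools, carriers, capitalize = TRUE) {
  n_words <- sample(6:12, 1)
  words <- sample(carriers, n_words, replace = TRUE)
  n_ent <- stats::rpois(1, config$entity_density)
  ents <- character(0); etypes <- character(0)
  if (n_ent > 0) {
    etypes <- sample(ENTITY_TYPES, n_ent, replace = TRUE,
                     prob = config$type_mixture)
    ents <- vapply(etypes, .entity_surface, character(1), pools = pools)
  }
  # splice entities (with optional cue words) at random word gaps; ent_ty
  # tracks, per piece, which entity type it carries ("" for carrier words)
  pieces <- words
  ent_ty <- character(length(pieces))
  for (j in seq_along(ents)) {
    at <- sample(seq_len(length(pieces) + 1L), 1)
    ins <- character(0); ins_ty <- character(0)
    if (stats::runif(1) < 0.4) { ins <- c(ins, sample(CUE_BEFORE, 1)); ins_ty <- c(ins_ty, "") }
    ins <- c(ins, ents[j]); ins_ty <- c(ins_ty, etypes[j])
    if (stats::runif(1) < 0.3) { ins <- c(ins, sample(CUE_AFTER, 1)); ins_ty <- c(ins_ty, "") }
    pieces <- append(pieces, ins, after = at - 1L)
    ent_ty <- append(ent_ty, ins_ty, after = at - 1L)
  }
  strs <- pieces
  if (capitalize && ent_ty[1] == "") {
    strs[1] <- paste0(toupper(substr(strs[1], 1, 1)), substr(strs[1], 2, nchar(strs[1])))
  }
  starts <- cumsum(c(0L, nchar(strs) + 1L))[seq_along(strs)]
  text <- paste0(paste(strs, collapse = " "), ".")
  ment <- if (any(nzchar(ent_ty))) {
    idx <- which(nzchar(ent_ty))
    as_mentions("", "ABSTRACT", starts[idx], starts[idx] + nchar(strs[idx]),
                strs[idx], ent_ty[idx])
  } else empty_mentions()
  list(text = text, mentions = ment)
}

#' Generate a synthetic annotated corpus
#'
#' Documents consist of a one-sentence title and several abstract sentences
#' of carrier English with chemical-like mentions planted according to the
#' configured type mixture: systematic names chain multiplier/size prefixes,
#' a stem and a chemical suffix (optionally with a locant like `1,2-`),
#' formulas are element-symbol/digit strings, abbreviations are short
#' capital runs, identifiers letter-digit codes, families plural suffixed
#' names, and so on. Annotations are offset-exact by construction, and the
#' same seed always reproduces the identical corpus.
#'
#' @param config A [synth_config()].
#' @return List with `documents` and `mentions` frames.
#' @export
generate_corpus <- function(config = synth_config()) {
  pools <- .stem_pools(config)
  carriers <- utils::head(CARRIER_WORDS, config$n_carrier)
  with_seed(config$seed, {
    docs <- vector("list", config$n_documents)
    ments <- vector("list", config$n_documents)
    for (i in seq_len(config$n_documents)) {
      doc_id <- sprintf("SYN%05d", i)
      title <- .make_sentence(config, pools, carriers)
      if (nrow(title$mentions)) title$mentions$section <- "TITLE"
      n_sent <- sample(config$sentences_per_doc[1]:config$sentences_per_doc[2], 1)
      sents <- lapply(seq_len(n_sent), function(s)
        .make_sentence(config, pools, carriers))
      offset <- 0L
      abstract_parts <- character(n_sent)
      sent_ments <- list()
      for (s in seq_len(n_sent)) {
        abstract_parts[s] <- sents[[s]]$text
        m <- sents[[s]]$mentions
        if (nrow(m)) {
          m$start <- m$start + offset
          m$end <- m$end + offset
          sent_ments[[length(sent_ments) + 1L]] <- m
        }
        offset <- offset + nchar(sents[[s]]$text) + 1L  # joining space
      }
      dm <- rbind(title$mentions, do.call(rbind, c(sent_ments, list(empty_mentions()))))
      dm$doc_id <- rep(doc_id, nrow(dm))
      docs[[i]] <- data.frame(doc_id = doc_id, title = title$text,
                              abstract = paste(abstract_parts, collapse = " "),
                              stringsAsFactors = FALSE)
      ments[[i]] <- dm
    }
    documents <- do.call(rbind, docs)
    mentions <- do.call(rbind, ments)
    rownames(documents) <- rownames(mentions) <- NULL
    # integrity by construction: verify before returning
    sect <- ifelse(mentions$section == "TITLE",
                   documents$title[match(mentions$doc_id, documents$doc_id)],
                   documents$abstract[match(mentions$doc_id, documents$doc_id)])
    stopifnot(identical(substr0(sect, mentions$start, mentions$end), mentions$text))
    list(documents = documents, mentions = mentions)
  })
}

#' Generate unlabeled text for word-representation training
#'
#' Emits whitespace-tokenized, lowercased sentences (one per line) drawn
#' from the same vocabulary as the labeled corpus -- including the held-out
#' stems, mirroring the situation where unsupervised text covers vocabulary
#' the annotated training set lacks.
#'
#' @param config A [synth_config()]; `n_documents` controls the volume
#'   (sentences = documents x sentences per document).
#' @return Character vector of tokenized sentences.
#' @export
generate_unlabeled <- function(config = synth_config()) {
  pools <- .stem_pools(config, all = TRUE)
  carriers <- utils::head(CARRIER_WORDS, config$n_carrier)
  with_seed(config$seed + 1L, {
    n_sent <- config$n_documents *
      round(mean(config$sentences_per_doc[1]:config$sentences_per_doc[2]))
    vapply(seq_len(n_sent), function(i) {
      s <- .make_sentence(config, pools, carriers, capitalize = FALSE)
      toks <- tokenize(s$text, section = "ABSTRACT")
      paste(tolower(toks$tokens$text), collapse = " ")
    }, character(1))
  })
}

#' Write a synthetic corpus to CHEMDNER-dialect files
#'
#' @param corpus A [generate_corpus()] result.
#' @param dir Output directory (created if missing).
#' @return Paths of the abstracts and annotations files.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ab <- file.path(dir, "abstracts.tsv")
  an <- file.path(dir, "annotations.tsv")
  write_abstracts(corpus$documents, ab)
  write_annotations(corpus$mentions, an)
  c(abstracts = ab, annotations = an)
}
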