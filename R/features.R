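# Per-token sparse binary features: bag-of-word, orthographic, morphological,
# POS, document structure, domain knowledge and word-representation families.
# Feature names are namespaced by family ("ortho:ALLCAPS", "bow:uni[-1]=the")
# and carry set semantics.

# The sixteen orthographic patterns. Each is tested verbatim with a
# Perl-compatible engine; unanchored patterns match anywhere in the token.
ORTHO_REGEXES <- c(
  ALLCAPS     = "^[A-Z]+$",
  INITCAP     = "^[A-Z].*",
  HASCAP      = "^.*[A-Z].*$",
  SINGLECAP   = "^[A-Z]$",
  PUNCTATION  = "^[,;:\\'\\\"]$",
  INITDIGIT   = "^[0-9].*",
  SINGLEDIGIT = "^[0-9]$",
  ALPHANUM    = ".*[A-Za-z].*[0-9].*|.*[0-9].*[A-Za-z].*",
  MANY_NUM    = "^[0-9]{1,2}(,[0-9]{1,2})+$",
  REAL_NUM    = "^-?[0-9]+[\\.][0-9]+$",
  INDASH      = "^([\\w+][\\-]+)+\\w+$",
  HASDIGIT    = ".*[0-9].*",
  IS_DASH     = "^[-]+$",
  ROMAN       = "^[IVXDLCM]+$",
  END_PUNC    = "^[.?!]$",
  CAPSMIX     = ".*[A-Z].*[a-z].*|.*[a-z].*[A-Z].*"
)

# Chemical-name affixes used as domain-knowledge lookups.
CHEM_PREFIXES <- c("alk", "meth", "eth", "prop", "but", "pent", "hex", "hept",
                   "oct", "non", "dec", "undec", "dodec", "eifcos",
                   "di", "tri", "tetra", "penta", "hexa", "hepta")
CHEM_SUFFIXES <- c("ane", "ene", "yne", "yl", "ol", "al", "oic", "one", "ate",
                   "amine", "amide")

.lex_cache <- new.env(parent = emptyenv())

#' Bundled chemical element lexicon
#'
#' @return Data frame with columns `symbol` and `name` for the 118 elements.
#' @export
chemical_elements <- function() {
  if (is.null(.lex_cache$elements)) {
    path <- system.file("extdata", "chemical_elements.tsv", package = "chemner")
    .lex_cache$elements <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .lex_cache$elements
}

#' Feature extraction configuration
#'
#' @param families Character vector of enabled feature families, a subset of
#'   `c("bow", "ortho", "morph", "pos", "struct", "domain", "wr")`. The
#'   default enables everything except `wr` (the baseline feature set).
#' @param window Integer pair `c(lower, upper)` with `lower <= 0 <= upper`;
#'   context window for bag-of-word and POS n-grams.
#' @param affix_lengths Integer range of prefix/suffix lengths for the
#'   morphological family.
#' @param lexicons Named list of user lexicons: each element a character
#'   vector of terms, or a path to a one-term-per-line UTF-8 file.
#' @param wr_models List of word-representation feature maps (see
#'   [wr_feature_map()]).
#' @param pos_tagger A function `function(tokens) -> character` returning one
#'   tag per token, or `NULL` for the bundled heuristic tagger
#'   ([heuristic_pos_tag()]).
#' @return A `feature_config` list.
#' @export
feature_config <- function(families = c("bow", "ortho", "morph", "pos", "struct", "domain"),
                           window = c(-2L, 2L),
                           affix_lengths = 2:5,
                           lexicons = list(),
                           wr_models = list(),
                           pos_tagger = NULL) {
  known <- c("bow", "ortho", "morph", "pos", "struct", "domain", "wr")
  if (length(setdiff(families, known))) {
    stop("unknown feature families: ", paste(setdiff(families, known), collapse = ", "))
  }
  stopifnot(length(window) == 2, window[1] <= 0, window[2] >= 0,
            all(affix_lengths >= 1))
  lexicons <- lapply(lexicons, function(lx) {
    if (is.character(lx) && length(lx) == 1 && file.exists(lx)) {
      lx <- readLines(lx, encoding = "UTF-8", warn = FALSE)
    } else if (is.character(lx) && length(lx) == 1 && grepl("[/\\\\]", lx)) {
      stop("unreadable lexicon file: ", lx)
    }
    tolower(lx[nzchar(lx)])
  })
  structure(list(families = families, window = as.integer(window),
                 affix_lengths = as.integer(affix_lengths),
                 lexicons = lexicons, wr_models = wr_models,
                 pos_tagger = pos_tagger),
            class = "feature_config")
}

# Window token with boundary symbol for out-of-range positions.
.window_word <- function(words, i) {
  ifelse(i < 1 | i > length(words), "<s>", words[pmax(1L, pmin(length(words), i))])
}

# Shared n-gram windowing for bag-of-word and POS families.
ngram_window_features <- function(items, i, window, ns) {
  offs <- window[1]:window[2]
  words <- .window_word(items, i + offs)
  feats <- paste0(ns, ":uni[", offs, "]=", words)
  if (length(offs) >= 2) {
    a <- seq_len(length(offs) - 1)
    feats <- c(feats, paste0(ns, ":bi[", offs[a], ",", offs[a + 1], "]=",
                             words[a], "_", words[a + 1]))
  }
  if (length(offs) >= 3) {
    a <- seq_len(length(offs) - 2)
    feats <- c(feats, paste0(ns, ":tri[", offs[a], ",", offs[a + 1], ",",
                             offs[a + 2], "]=",
                             words[a], "_", words[a + 1], "_", words[a + 2]))
  }
  feats
}

#' Bag-of-word n-gram features
#'
#' Unigrams, bigrams and trigrams of (lowercased) tokens over a context
#' window around position `i`. Out-of-range positions contribute the boundary
#' symbol `<s>`.
#'
#' @param tokens Character vector of token texts for one sentence.
#' @param i Position (1-based).
#' @param window Integer pair, default `c(-2, 2)`.
#' @return Character vector of feature names.
#' @export
bow_features <- function(tokens, i, window = c(-2L, 2L)) {
  stopifnot(i >= 1, i <= length(tokens))
  ngram_window_features(tolower(tokens), i, window, "bow")
}

#' Orthographic features
#'
#' One feature per matching pattern among the sixteen word-formation regexes
#' (capitalization, digits, dashes, Roman numerals, ...).
#'
#' @param token_text A single token string.
#' @return Character vector of feature names, e.g. `"ortho:ALLCAPS"`.
#' @export
orthographic_features <- function(token_text) {
  hit <- vapply(ORTHO_REGEXES, function(rx) grepl(rx, token_text, perl = TRUE),
                logical(1))
  paste0("ortho:", names(ORTHO_REGEXES)[hit])
}

# Word shape: uppercase -> A, lowercase -> a, digit -> 0, other -> x.
word_shape <- function(token_text) {
  s <- gsub("[A-Z]", "A", token_text)
  s <- gsub("[a-z]", "a", s)
  s <- gsub("[0-9]", "0", s)
  gsub("[^Aa0]", "x", s)
}

collapse_shape <- function(shape) gsub("(.)\\1+", "\\1", shape)

#' Morphological features
#'
#' Prefixes and suffixes of the configured lengths (only where the token is
#' at least that long) plus the word shape (`A`/`a`/`0`/`x` per character)
#' and its run-collapsed form.
#'
#' @param token_text A single token string.
#' @param lengths Affix lengths, default `2:5`.
#' @return Character vector of feature names.
#' @export
morphological_features <- function(token_text, lengths = 2:5) {
  n <- nchar(token_text)
  ks <- lengths[lengths <= n]
  feats <- character(0)
  if (length(ks)) {
    feats <- c(paste0("morph:prefix", ks, "=", substr(rep(token_text, length(ks)), 1, ks)),
               paste0("morph:suffix", ks, "=", substring(rep(token_text, length(ks)), n - ks + 1)))
  }
  shp <- word_shape(token_text)
  c(feats, paste0("morph:shape=", shp), paste0("morph:cshape=", collapse_shape(shp)))
}

#' POS n-gram features
#'
#' Same windowing scheme as [bow_features()] over the POS tag sequence.
#'
#' @param pos_tags Character vector of tags aligned to the sentence tokens.
#' @param i Position (1-based).
#' @param window Integer pair, default `c(-2, 2)`.
#' @return Character vector of feature names.
#' @export
pos_features <- function(pos_tags, i, window = c(-2L, 2L)) {
  stopifnot(i >= 1, i <= length(pos_tags))
  ngram_window_features(pos_tags, i, window, "pos")
}

#' Document structure feature
#'
#' @param token_text Token string (unused; the feature only depends on the
#'   section).
#' @param section `"TITLE"` or `"ABSTRACT"`.
#' @return `"struct:in_title"` when the token sits in the title, else an
#'   empty character vector.
#' @export
structure_feature <- function(token_text, section) {
  if (identical(section, "TITLE")) "struct:in_title" else character(0)
}

#' Domain-knowledge features
#'
#' Lookups against chemical-name affix lists, the periodic table, and any
#' user-supplied lexicons (e.g. drug name lists).
#'
#' @param token_text A single token string.
#' @param lexicons Named list of lowercased term vectors (user lexicons).
#' @return Character vector of feature names, e.g. `"domain:suffix=ane"`.
#' @export
domain_features <- function(token_text, lexicons = list()) {
  lower <- tolower(token_text)
  feats <- character(0)
  pre <- CHEM_PREFIXES[startsWith(lower, CHEM_PREFIXES)]
  if (length(pre)) feats <- c(feats, paste0("domain:prefix=", pre))
  suf <- CHEM_SUFFIXES[endsWith(lower, CHEM_SUFFIXES)]
  if (length(suf)) feats <- c(feats, paste0("domain:suffix=", suf))
  el <- chemical_elements()
  if (token_text %in% el$symbol || lower %in% el$name) {
    feats <- c(feats, "domain:element")
  }
  for (nm in names(lexicons)) {
    if (lower %in% lexicons[[nm]]) feats <- c(feats, paste0("domain:lex=", nm))
  }
  feats
}

#' Word-representation features
#'
#' Discrete features from trained unsupervised models: Brown cluster bit-path
#' prefixes at lengths 4, 6, 10 and 20 (a word whose path is shorter than 4
#' emits its full path), and k-means cluster ids for random-indexing and
#' skip-gram vectors. Out-of-vocabulary words emit `"wr:<model>:UNK"`.
#'
#' @param token_text A single token string (lowercased for lookup).
#' @param wr_models List of [wr_feature_map()] objects.
#' @return Character vector of feature names.
#' @export
wr_features <- function(token_text, wr_models = list()) {
  if (length(wr_models) == 0) return(character(0))
  lower <- tolower(token_text)
  unlist(lapply(wr_models, function(m) wr_lookup(m, lower)), use.names = FALSE)
}

#' Heuristic POS tagger
#'
#' A small rule-cascade fallback used when no external tagger is plugged in:
#' coarse tags from character classes and common suffixes. Not a linguistic
#' tagger; it exists so POS n-gram features have a deterministic, dependency
#' free source.
#'
#' @param tokens Character vector of token texts.
#' @return Character vector of coarse tags.
#' @export
heuristic_pos_tag <- function(tokens) {
  tag <- rep("NN", length(tokens))
  tag[grepl("^[0-9.,%-]+$", tokens)] <- "CD"
  tag[grepl("^[[:punct:]]$", tokens)] <- "PUNC"
  low <- tolower(tokens)
  tag[low %in% c("the", "a", "an", "this", "that", "these", "those")] <- "DT"
  tag[low %in% c("of", "in", "on", "at", "by", "with", "from", "to", "for",
                 "under", "during", "after", "before", "between")] <- "IN"
  tag[low %in% c("and", "or", "but", "nor")] <- "CC"
  tag[low %in% c("is", "are", "was", "were", "be", "been", "has", "have",
                 "had", "can", "may", "could", "would", "should")] <- "VB"
  tag[grepl("(ed|ated|ized)$", low) & tag == "NN"] <- "VBD"
  tag[grepl("ing$", low) & tag == "NN"] <- "VBG"
  tag[grepl("ly$", low) & tag == "NN"] <- "RB"
  tag[grepl("(ive|ous|ful|ant|ent|ic|al)$", low) & tag == "NN"] <- "JJ"
  tag[grepl("^[A-Z]", tokens) & tag == "NN"] <- "NNP"
  tag
}

#' Extract feature vectors for a token sequence
#'
#' Per-token union of all enabled feature families. Window features (bag of
#' word, POS) never cross sentence boundaries. Deterministic given inputs
#' and configuration.
#'
#' @param tokens A [token_sequence()].
#' @param config A [feature_config()].
#' @return A list with one character vector of feature names per token.
#' @export
extract_features <- function(tokens, config = feature_config()) {
  tok <- tokens$tokens
  n <- nrow(tok)
  out <- vector("list", n)
  if (n == 0) return(out)
  fam <- config$families
  pos_all <- NULL
  if ("pos" %in% fam) {
    tagger <- config$pos_tagger
    if (is.null(tagger)) tagger <- heuristic_pos_tag
    pos_all <- tryCatch(tagger(tok$text), error = function(e) NULL)
    if (is.null(pos_all) || length(pos_all) != n) {
      warning("POS tagger unavailable or misaligned; disabling the pos family")
      pos_all <- NULL
    }
  }
  per_tok_cache <- new.env(parent = emptyenv())
  token_level <- function(text) {
    key <- text
    hit <- per_tok_cache[[key]]
    if (!is.null(hit)) return(hit)
    f <- character(0)
    if ("ortho" %in% fam) f <- c(f, orthographic_features(text))
    if ("morph" %in% fam) f <- c(f, morphological_features(text, config$affix_lengths))
    if ("domain" %in% fam) f <- c(f, domain_features(text, config$lexicons))
    if ("wr" %in% fam) f <- c(f, wr_features(text, config$wr_models))
    per_tok_cache[[key]] <- f
    f
  }
  struct_f <- if ("struct" %in% fam) structure_feature("", tokens$section) else character(0)
  for (s in unique(tok$sentence_index)) {
    idx <- which(tok$sentence_index == s)
    words <- tok$text[idx]
    ptags <- if (!is.null(pos_all)) pos_all[idx] else NULL
    for (j in seq_along(idx)) {
      f <- token_level(words[j])
      if ("bow" %in% fam) f <- c(f, bow_features(words, j, config$window))
      if (!is.null(ptags)) f <- c(f, pos_features(ptags, j, config$window))
      out[[idx[j]]] <- unique(c(f, struct_f))
    }
  }
  out
}

#' Dump extracted features in CRFsuite-style text format
#'
#' One token per line: label, then tab-separated feature names; blank line
#' between sentences.
#'
#' @param tokens A [token_sequence()].
#' @param features Output of [extract_features()].
#' @param labels Per-token labels (default all `O`).
#' @param path Output path.
#' @export
write_feature_dump <- function(tokens, features, labels = NULL, path) {
  tok <- tokens$tokens
  if (is.null(labels)) labels <- rep("O", nrow(tok))
  lines <- character(0)
  for (s in unique(tok$sentence_index)) {
    idx <- which(tok$sentence_index == s)
    lines <- c(lines, vapply(idx, function(i) {
      paste(c(labels[i], sort(features[[i]])), collapse = "\t")
    }, character(1)), "")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
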