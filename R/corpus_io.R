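# Reading and writing the CHEMDNER file dialects, span <-> BIO conversion,
# and corpus statistics.
#
# All character offsets are 0-based, half-open, and local to their section
# (title and abstract are separately indexed coordinate spaces). Files are
# UTF-8.

#' Read an abstracts file
#'
#' Parses a tab-separated abstracts file with one document per line:
#' `doc_id<TAB>title<TAB>abstract`.
#'
#' @param path Path to a UTF-8 encoded TSV file.
#' @return A data frame with columns `doc_id`, `title`, `abstract`, one row
#'   per document, in file order.
#' @export
read_abstracts <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) {
    return(data.frame(doc_id = character(), title = character(),
                      abstract = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3)) {
    bad <- which(nf != 3)[1]
    stop("malformed abstracts line ", lineno[bad], ": expected 3 tab-separated fields, got ", nf[bad])
  }
  m <- do.call(rbind, parts)
  docs <- data.frame(doc_id = m[, 1], title = m[, 2], abstract = m[, 3],
                     stringsAsFactors = FALSE)
  if (anyDuplicated(docs$doc_id)) {
    stop("duplicate document id: ", docs$doc_id[duplicated(docs$doc_id)][1])
  }
  if (any(!nzchar(docs$doc_id))) stop("empty document id")
  docs
}

#' Write an abstracts file
#'
#' @param documents A data frame with columns `doc_id`, `title`, `abstract`.
#' @param path Output path.
#' @export
write_abstracts <- function(documents, path) {
  lines <- paste(documents$doc_id, documents$title, documents$abstract, sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an annotations file
#'
#' Parses a tab-separated annotations file with one mention per line:
#' `doc_id<TAB>T|A<TAB>start<TAB>end<TAB>text<TAB>type`. Every mention's text
#' is verified against the corresponding document substring, so offsets in
#' the returned frame are trustworthy by construction.
#'
#' @param path Path to a UTF-8 encoded TSV file.
#' @param documents The document frame (from [read_abstracts()]) the
#'   annotations refer to.
#' @return A mention data frame with columns `doc_id`, `section`
#'   (`"TITLE"`/`"ABSTRACT"`), `start`, `end` (0-based half-open), `text`,
#'   `etype`.
#' @export
read_annotations <- function(path, documents) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) return(empty_mentions())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6)) {
    bad <- which(nf != 6)[1]
    stop("malformed annotation line ", lineno[bad], ": expected 6 tab-separated fields, got ", nf[bad])
  }
  m <- do.call(rbind, parts)
  etype <- m[, 6]
  bad_type <- !(etype %in% ENTITY_TYPES)
  if (any(bad_type)) {
    stop("unknown entity type '", etype[bad_type][1], "' on line ", lineno[bad_type][1])
  }
  mentions <- as_mentions(m[, 1], section_from_code(m[, 2]),
                          as.integer(m[, 3]), as.integer(m[, 4]), m[, 5], etype)
  idx <- match(mentions$doc_id, documents$doc_id)
  if (anyNA(idx)) {
    stop("annotation refers to unknown document: ", mentions$doc_id[is.na(idx)][1])
  }
  sect_text <- ifelse(mentions$section == "TITLE",
                      documents$title[idx], documents$abstract[idx])
  bad_rng <- mentions$start < 0 | mentions$end <= mentions$start |
    mentions$end > nchar(sect_text)
  if (any(bad_rng)) {
    i <- which(bad_rng)[1]
    stop("offset out of range for ", mentions$doc_id[i], " [",
         mentions$start[i], ",", mentions$end[i], ")")
  }
  actual <- substr0(sect_text, mentions$start, mentions$end)
  bad_txt <- actual != mentions$text
  if (any(bad_txt)) {
    i <- which(bad_txt)[1]
    stop("annotation text mismatch for ", mentions$doc_id[i], " [",
         mentions$start[i], ",", mentions$end[i], "): '", actual[i],
         "' != '", mentions$text[i], "'")
  }
  check_no_overlap(mentions, "gold mentions")
  mentions
}

#' Write an annotations file
#'
#' @param mentions A mention data frame.
#' @param path Output path.
#' @export
write_annotations <- function(mentions, path) {
  lines <- paste(mentions$doc_id, section_to_code(mentions$section),
                 mentions$start, mentions$end, mentions$text, mentions$etype,
                 sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Label alphabet: untyped BIO (default) or one B/I pair per entity type.
label_set <- function(typed = FALSE) {
  if (typed) c(paste0(rep(c("B-", "I-"), each = length(ENTITY_TYPES)), ENTITY_TYPES), "O")
  else c("B", "I", "O")
}

#' Encode mention spans as per-token BIO labels
#'
#' The token that starts a mention receives `B`, every further token whose
#' span intersects the mention receives `I`, and all remaining tokens `O`.
#' A mention boundary that falls strictly inside a token raises a warning and
#' the whole token is labeled as part of the mention.
#'
#' @param tokens A [token_sequence()].
#' @param mentions Mention rows for the same document-section (offsets in the
#'   section's coordinates).
#' @param typed If `TRUE` emit typed labels (`B-SYSTEMATIC`, ...), otherwise
#'   plain `B`/`I`/`O`.
#' @return A character vector of labels, one per token.
#' @export
spans_to_bio <- function(tokens, mentions, typed = FALSE) {
  tok <- tokens$tokens
  labels <- rep("O", nrow(tok))
  if (nrow(mentions) == 0) return(labels)
  check_no_overlap(mentions)
  ord <- order(mentions$start)
  for (i in ord) {
    s <- mentions$start[i]; e <- mentions$end[i]
    hit <- which(tok$end > s & tok$start < e)
    if (length(hit) == 0) next
    if (tok$start[hit[1]] < s || tok$end[hit[length(hit)]] > e) {
      warning("mention boundary [", s, ",", e, ") falls inside a token; ",
              "labeling whole token(s)")
    }
    suffix <- if (typed) paste0("-", mentions$etype[i]) else ""
    labels[hit[1]] <- paste0("B", suffix)
    if (length(hit) > 1) labels[hit[-1]] <- paste0("I", suffix)
  }
  labels
}

#' Decode BIO labels into mention spans
#'
#' Maximal `B (I)*` runs become mentions spanning from the first token's
#' start to the last token's end. An orphan `I` (at sequence start or after
#' `O`) is repaired to `B` before decoding.
#'
#' @param tokens A [token_sequence()].
#' @param labels Character labels, one per token (`B`/`I`/`O`, optionally
#'   type-suffixed).
#' @param doc_id Document id stamped on the output rows.
#' @return A mention data frame; `etype` is `NO_CLASS` for untyped labels.
#' @export
bio_to_spans <- function(tokens, labels, doc_id = NA_character_) {
  tok <- tokens$tokens
  if (length(labels) != nrow(tok)) {
    stop("label sequence length ", length(labels), " != token count ", nrow(tok))
  }
  labels <- repair_bio(labels)
  base <- sub("-.*$", "", labels)
  out <- empty_mentions()
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    if (base[i] == "B") {
      j <- i
      while (j < n && base[j + 1L] == "I") j <- j + 1L
      s <- tok$start[i]; e <- tok$end[j]
      etype <- if (grepl("-", labels[i], fixed = TRUE))
        sub("^[BI]-", "", labels[i]) else "NO_CLASS"
      out <- rbind(out, as_mentions(doc_id, tokens$section, s, e,
                                    substr0(tokens$source_text, s, e), etype))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Orphan I (after O or at sequence start) becomes B, keeping any type suffix.
repair_bio <- function(labels) {
  base <- sub("-.*$", "", labels)
  prev <- c("O", base[-length(base)])
  orphan <- base == "I" & prev == "O"
  labels[orphan] <- sub("^I", "B", labels[orphan])
  labels
}

#' Write a predictions file
#'
#' One line per mention: `doc_id<TAB>T|A:start:end<TAB>rank<TAB>confidence`.
#' Ranks are assigned per document by descending confidence; ties break by
#' section (title before abstract) and then start offset.
#'
#' @param mentions A mention data frame.
#' @param scores Confidence in `[0, 1]` per mention.
#' @param path Output path.
#' @export
write_predictions <- function(mentions, scores, path) {
  stopifnot(length(scores) == nrow(mentions))
  if (length(scores) && (any(scores < 0) || any(scores > 1))) {
    stop("confidence scores must lie in [0, 1]")
  }
  lines <- character(0)
  for (d in unique(mentions$doc_id)) {
    sel <- which(mentions$doc_id == d)
    m <- mentions[sel, , drop = FALSE]
    sc <- scores[sel]
    ord <- order(-sc, match(m$section, SECTION_LEVELS), m$start)
    m <- m[ord, , drop = FALSE]
    sc <- sc[ord]
    lines <- c(lines, paste0(m$doc_id, "\t", section_to_code(m$section), ":",
                             m$start, ":", m$end, "\t", seq_along(sel), "\t",
                             format(sc, trim = TRUE)))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a predictions file
#'
#' Inverse of [write_predictions()]; mention texts are recovered from the
#' documents so the result passes the same integrity checks as gold
#' annotations.
#'
#' @param path Predictions TSV path.
#' @param documents Document frame the predictions refer to.
#' @return A list with `mentions` (mention frame, `etype = NO_CLASS`) and
#'   `scores` (numeric confidences).
#' @export
read_predictions <- function(path, documents) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(list(mentions = empty_mentions(), scores = numeric(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 4)) stop("malformed predictions line")
  m <- do.call(rbind, parts)
  loc <- strsplit(m[, 2], ":", fixed = TRUE)
  if (any(lengths(loc) != 3)) stop("malformed span locator in predictions file")
  l <- do.call(rbind, loc)
  mentions <- as_mentions(m[, 1], section_from_code(l[, 1]),
                          as.integer(l[, 2]), as.integer(l[, 3]), "", "NO_CLASS")
  idx <- match(mentions$doc_id, documents$doc_id)
  if (anyNA(idx)) stop("prediction refers to unknown document")
  sect_text <- ifelse(mentions$section == "TITLE", documents$title[idx],
                      documents$abstract[idx])
  mentions$text <- substr0(sect_text, mentions$start, mentions$end)
  list(mentions = mentions, scores = as.numeric(m[, 4]))
}

#' Per-type mention counts
#'
#' @param mentions A mention data frame.
#' @return A list with `counts` (named integer vector over all eight entity
#'   types) and `total`.
#' @export
corpus_statistics <- function(mentions) {
  counts <- table(factor(mentions$etype, levels = ENTITY_TYPES))
  counts <- stats::setNames(as.integer(counts), ENTITY_TYPES)
  list(counts = counts, total = sum(counts))
}

#' Write tokens in CoNLL-style vertical format
#'
#' One token per line (`token<TAB>start<TAB>end<TAB>pos<TAB>label`), one
#' blank line between sentences.
#'
#' @param tokens A [token_sequence()].
#' @param labels Per-token labels (defaults to all `O`).
#' @param pos Per-token POS tags (defaults to `_`).
#' @param path Output path.
#' @export
write_conll <- function(tokens, labels = NULL, pos = NULL, path) {
  tok <- tokens$tokens
  if (is.null(labels)) labels <- rep("O", nrow(tok))
  if (is.null(pos)) pos <- rep("_", nrow(tok))
  lines <- character(0)
  for (s in unique(tok$sentence_index)) {
    sel <- tok$sentence_index == s
    lines <- c(lines,
               paste(tok$text[sel], tok$start[sel], tok$end[sel],
                     pos[sel], labels[sel], sep = "\t"),
               "")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read CoNLL-style vertical format
#'
#' @param path Input path.
#' @return A data frame with columns `text`, `start`, `end`, `pos`, `label`,
#'   `sentence_index`.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sent <- cumsum(!nzchar(lines))
  keep <- nzchar(lines)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(parts) != 5)) stop("malformed CoNLL line")
  m <- do.call(rbind, parts)
  sidx <- sent[keep]
  data.frame(text = m[, 1], start = as.integer(m[, 2]), end = as.integer(m[, 3]),
             pos = m[, 4], label = m[, 5],
             sentence_index = match(sidx, unique(sidx)),
             stringsAsFactors = FALSE)
}
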