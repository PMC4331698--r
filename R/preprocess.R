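# Rule-based sentence boundary detection and tokenization with exact
# character-offset bookkeeping.

#' Token sequence container
#'
#' Bundles the tokens of one document section with the source text they were
#' cut from. Offsets are 0-based half-open into `source_text`, so
#' `substr(source_text, start + 1, end)` always reproduces `text`.
#'
#' @param tokens Data frame with columns `text`, `start`, `end`,
#'   `sentence_index`.
#' @param section `"TITLE"` or `"ABSTRACT"`.
#' @param source_text The section text the offsets refer to.
#' @return An object of class `token_sequence`.
#' @export
token_sequence <- function(tokens, section, source_text) {
  stopifnot(all(c("text", "start", "end", "sentence_index") %in% names(tokens)),
            section %in% SECTION_LEVELS)
  if (nrow(tokens) > 0) {
    got <- substr0(source_text, tokens$start, tokens$end)
    if (any(got != tokens$text)) {
      i <- which(got != tokens$text)[1]
      stop("token ", i, " ('", tokens$text[i], "') does not match source substring '", got[i], "'")
    }
    if (any(diff(tokens$start) <= 0) && nrow(tokens) > 1) {
      stop("tokens must be in strictly increasing offset order")
    }
    if (any(tokens$end[-nrow(tokens)] > tokens$start[-1])) stop("tokens overlap")
  }
  structure(list(tokens = tokens, section = section, source_text = source_text),
            class = "token_sequence")
}

#' @export
print.token_sequence <- function(x, ...) {
  cat("<token_sequence> ", x$section, ": ", nrow(x$tokens), " tokens, ",
      length(unique(x$tokens$sentence_index)), " sentence(s)\n", sep = "")
  invisible(x)
}

# Words before a sentence-final period that should not trigger a split.
ABBREV_GUARD <- c("al", "etc", "vs", "cf", "ca", "resp", "approx",
                  "e.g", "i.e", "Fig", "Figs", "Eq", "Eqs", "Ref", "Refs",
                  "Dr", "Prof", "St", "No", "vol", "Vol")

#' Split text into sentence spans
#'
#' A sentence boundary is placed after a run of `.`, `?` or `!` that is
#' followed by whitespace and an uppercase letter or digit, unless the word
#' preceding the period is on a short abbreviation guard list (e.g.
#' `"et al."`, `"i.e."`) or is a single capital (initials). Decimal points
#' never split because they are not followed by whitespace.
#'
#' @param text Section text.
#' @return A data frame with columns `start`, `end`: 0-based half-open spans,
#'   ordered and non-overlapping, together covering every non-whitespace
#'   character.
#' @export
split_sentences <- function(text) {
  empty <- data.frame(start = integer(), end = integer())
  n <- nchar(text)
  if (n == 0 || !grepl("[^[:space:]]", text)) return(empty)
  cand <- gregexpr("[.?!]+(?=[[:space:]]+[A-Z0-9])", text, perl = TRUE)[[1]]
  breaks <- integer(0)
  if (cand[1] != -1) {
    ends <- as.integer(cand) + attr(cand, "match.length") - 1L  # 1-based last punct char
    for (e in ends) {
      run_start <- as.integer(cand[ends == e][1])
      before <- substr(text, 1, run_start - 1L)
      word <- regmatches(before, regexpr("[A-Za-z][A-Za-z.]*$", before))
      guarded <- length(word) == 1 &&
        (word %in% ABBREV_GUARD || grepl("^[A-Z]$", word))
      if (!guarded) breaks <- c(breaks, e)  # sentence ends after position e
    }
  }
  starts1 <- c(1L, breaks + 1L)            # 1-based candidate sentence starts
  ends1 <- c(breaks, n)                    # 1-based inclusive ends
  out <- empty
  for (i in seq_along(starts1)) {
    seg <- substr(text, starts1[i], ends1[i])
    m <- regexpr("[^[:space:]]", seg)
    if (m == -1) next
    first <- starts1[i] + as.integer(m) - 1L
    last_rel <- regexpr("[^[:space:]][[:space:]]*$", seg)
    last <- starts1[i] + as.integer(last_rel) - 1L
    out <- rbind(out, data.frame(start = first - 1L, end = last))
  }
  out
}

# Characters always isolated as single-character tokens; '.' and ',' are kept
# inside a token only between two digits (decimals "7.4", locants "1,2").
PUNCT_SPLIT <- c("-", "(", ")", "[", "]", "{", "}", ",", ".", ";", ":", "!",
                 "?", "/", "\\", "\"", "'", "%", "&", "+", "=", "<", ">", "*")

# Split one whitespace-free chunk into token substrings (returns 1-based
# start positions within the chunk and the pieces).
split_chunk <- function(chunk) {
  chars <- strsplit(chunk, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 1) return(list(starts = 1L, pieces = chunk))
  is_punct <- chars %in% PUNCT_SPLIT
  if (any(is_punct)) {
    digit <- grepl("[0-9]", chars)
    for (i in which(is_punct)) {
      if (chars[i] %in% c(".", ",") && i > 1 && i < n && digit[i - 1] && digit[i + 1]) {
        is_punct[i] <- FALSE
      }
    }
  }
  # boundary before i if punctuation state changes or either side is punct
  cut <- logical(n)  # cut[i]: new token starts at i
  cut[1] <- TRUE
  for (i in 2:n) cut[i] <- is_punct[i] || is_punct[i - 1]
  starts <- which(cut)
  ends <- c(starts[-1] - 1L, n)
  list(starts = starts,
       pieces = substring(chunk, starts, ends))
}

#' Tokenize section text
#'
#' Splits on whitespace, then isolates punctuation (hyphen, brackets, comma,
#' period, slash, ...) as single-character tokens. Decimal points and commas
#' flanked by digits stay inside their token (`"7.4"`, `"1,2"` remain
#' whole), so `"N-acetyl-L cysteine"` becomes the six tokens
#' `N - acetyl - L cysteine`. Greek letters and other non-ASCII characters
#' are kept attached to their word; no Unicode normalization is applied, so
#' offsets stay exact.
#'
#' @param text Section text.
#' @param sentence_spans Optional precomputed [split_sentences()] result.
#' @param section `"TITLE"` or `"ABSTRACT"`.
#' @return A [token_sequence()].
#' @export
tokenize <- function(text, sentence_spans = NULL, section = "ABSTRACT") {
  if (is.null(sentence_spans)) sentence_spans <- split_sentences(text)
  rows <- list()
  for (si in seq_len(nrow(sentence_spans))) {
    s0 <- sentence_spans$start[si]; e0 <- sentence_spans$end[si]
    seg <- substr0(text, s0, e0)
    m <- gregexpr("[^[:space:]]+", seg)[[1]]
    if (m[1] == -1) next
    chunk_starts <- as.integer(m)
    chunk_lens <- attr(m, "match.length")
    chunks <- regmatches(seg, list(m))[[1]]
    for (ci in seq_along(chunks)) {
      sp <- split_chunk(chunks[ci])
      abs_start <- s0 + chunk_starts[ci] - 1L + sp$starts - 1L  # 0-based
      rows[[length(rows) + 1L]] <- data.frame(
        text = sp$pieces, start = abs_start,
        end = abs_start + nchar(sp$pieces), sentence_index = si,
        stringsAsFactors = FALSE)
    }
  }
  tok <- if (length(rows)) do.call(rbind, rows) else
    data.frame(text = character(), start = integer(), end = integer(),
               sentence_index = integer(), stringsAsFactors = FALSE)
  rownames(tok) <- NULL
  token_sequence(tok, section, text)
}

#' Re-anchor token offsets into another rendering of the same text
#'
#' Greedy left-to-right matching: each token is located at its first
#' occurrence at or after the previous token's end. Fails loudly when a token
#' cannot be found rather than silently shifting offsets.
#'
#' @param tokens A [token_sequence()] whose offsets refer to a processed
#'   (e.g. whitespace-normalized) variant of the text.
#' @param original_text The original section text to re-anchor into.
#' @return A [token_sequence()] with offsets into `original_text`.
#' @export
realign <- function(tokens, original_text) {
  tok <- tokens$tokens
  cursor <- 0L  # 0-based position from which to search
  starts <- integer(nrow(tok))
  for (i in seq_len(nrow(tok))) {
    rest <- substr(original_text, cursor + 1L, nchar(original_text))
    pos <- regexpr(tok$text[i], rest, fixed = TRUE)
    if (pos == -1) {
      stop("realign: token ", i, " ('", tok$text[i],
           "') not found in original text after offset ", cursor)
    }
    starts[i] <- cursor + as.integer(pos) - 1L
    cursor <- starts[i] + nchar(tok$text[i])
  }
  tok$start <- starts
  tok$end <- starts + nchar(tok$text)
  token_sequence(tok, tokens$section, original_text)
}

# Convenience: sentence-split + tokenize one section.
tokenize_section <- function(text, section) {
  tokenize(text, split_sentences(text), section = section)
}
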