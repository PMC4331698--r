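# Deterministic repair rules applied to decoded mentions:
#   rule 1: merge an entity that starts where another ends
#   rule 2: drop entities made only of numbers and punctuation
#   rule 3: extend left over an unmatched ')' to the previous '('
#   rule 4: extend right over an unmatched '(' to the next ')'
# apply_postprocess() runs them in the order 2, 3, 4, 1, 2 and logs every
# modification with its rule id.

# Section text lookup for one mention row.
.section_text <- function(documents, doc_id, section) {
  r <- match(doc_id, documents$doc_id)
  if (is.na(r)) stop("mention refers to unknown document ", doc_id)
  if (section == "TITLE") documents$title[r] else documents$abstract[r]
}

.trace_row <- function(rule, doc_id, section, before, after) {
  data.frame(rule = rule, doc_id = doc_id, section = section,
             before = before, after = after, stringsAsFactors = FALSE)
}

empty_trace <- function() {
  data.frame(rule = integer(), doc_id = character(), section = character(),
             before = character(), after = character(), stringsAsFactors = FALSE)
}

#' Rule 1: merge chained entities
#'
#' Within one document-section, whenever one mention starts exactly where
#' another ends, the pair is replaced by their union span; applied to
#' fixpoint so whole chains collapse.
#'
#' @param mentions Mention rows of one document-section, with `text`
#'   consistent with `section_text`.
#' @param section_text The section's source text.
#' @return Merged mention rows.
#' @export
rule1_merge_chained <- function(mentions, section_text) {
  if (nrow(mentions) < 2) return(mentions)
  m <- mentions[order(mentions$start), , drop = FALSE]
  repeat {
    merged <- FALSE
    for (i in seq_len(nrow(m) - 1)) {
      if (m$end[i] == m$start[i + 1]) {
        m$end[i] <- m$end[i + 1]
        m$text[i] <- substr0(section_text, m$start[i], m$end[i])
        m <- m[-(i + 1), , drop = FALSE]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  rownames(m) <- NULL
  m
}

#' Rule 2: drop number/punctuation-only entities
#'
#' @param mentions Mention rows.
#' @return Rows whose text contains at least one letter.
#' @export
rule2_drop_numeric <- function(mentions) {
  keep <- grepl("[[:alpha:]]", mentions$text)
  out <- mentions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Count of unmatched ')' (first element) and unmatched '(' (second) in a
# string, by simple counter balance over parentheses only.
paren_balance <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  open <- 0L; unmatched_close <- 0L
  for (ch in chars) {
    if (ch == "(") open <- open + 1L
    else if (ch == ")") {
      if (open > 0L) open <- open - 1L else unmatched_close <- unmatched_close + 1L
    }
  }
  c(unmatched_close = unmatched_close, unmatched_open = open)
}

#' Rule 3: repair an unmatched closing parenthesis
#'
#' If the mention text contains a `)` with no matching `(` inside, the start
#' is extended left to the nearest preceding `(` in the source text. With no
#' `(` anywhere to the left the mention is returned unchanged.
#'
#' @param mention A single mention row.
#' @param section_text The section's source text.
#' @return The (possibly extended) mention row.
#' @export
rule3_fix_unmatched_close <- function(mention, section_text) {
  if (paren_balance(mention$text)["unmatched_close"] == 0) return(mention)
  before <- substr0(section_text, 0, mention$start)
  pos <- regexpr("\\([^(]*$", before)
  if (pos == -1) return(mention)
  mention$start <- as.integer(pos) - 1L
  mention$text <- substr0(section_text, mention$start, mention$end)
  mention
}

#' Rule 4: repair an unmatched opening parenthesis
#'
#' Symmetric to [rule3_fix_unmatched_close()]: an unmatched `(` extends the
#' mention right to the nearest following `)` in the source text, if any.
#'
#' @param mention A single mention row.
#' @param section_text The section's source text.
#' @return The (possibly extended) mention row.
#' @export
rule4_fix_unmatched_open <- function(mention, section_text) {
  if (paren_balance(mention$text)["unmatched_open"] == 0) return(mention)
  after <- substr(section_text, mention$end + 1L, nchar(section_text))
  pos <- regexpr(")", after, fixed = TRUE)
  if (pos == -1) return(mention)
  mention$end <- mention$end + as.integer(pos)
  mention$text <- substr0(section_text, mention$start, mention$end)
  mention
}

# Drop exact-duplicate spans and resolve overlaps (keep the earlier, longer
# span) so the output is a valid non-overlapping mention set.
.dedupe_overlaps <- function(m) {
  if (nrow(m) < 2) return(m)
  m <- m[order(m$start, -(m$end - m$start)), , drop = FALSE]
  keep <- rep(TRUE, nrow(m))
  last_end <- -1L
  for (i in seq_len(nrow(m))) {
    if (m$start[i] < last_end) keep[i] <- FALSE
    else last_end <- m$end[i]
  }
  out <- m[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply all post-processing rules
#'
#' Rules run in the order 2, 3, 4, 1, then 2 again: numeric fragments are
#' purged first, bracket repairs may move boundaries, adjacency merges run
#' on the repaired spans, and the final pass removes any numeric mention a
#' merge could have formed. The output is non-overlapping, text-consistent
#' and idempotent under re-application; every modification is logged.
#'
#' @param mentions Mention frame (realigned to original text).
#' @param documents Document frame the mentions refer to.
#' @return List with `mentions` (repaired frame) and `trace` (one row per
#'   rule application: rule id, before/after span).
#' @export
apply_postprocess <- function(mentions, documents) {
  trace <- empty_trace()
  out <- empty_mentions()
  key <- paste(mentions$doc_id, mentions$section)
  for (k in unique(key)) {
    m <- mentions[key == k, , drop = FALSE]
    stext <- .section_text(documents, m$doc_id[1], m$section[1])
    span_str <- function(x) paste0("[", x$start, ",", x$end, ") '", x$text, "'")

    # rule 2
    dropped <- m[!grepl("[[:alpha:]]", m$text), , drop = FALSE]
    for (i in seq_len(nrow(dropped))) {
      trace <- rbind(trace, .trace_row(2L, dropped$doc_id[i], dropped$section[i],
                                       span_str(dropped[i, ]), "<removed>"))
    }
    m <- rule2_drop_numeric(m)

    # rules 3 and 4 (iterated: an extension can expose a further unmatched
    # bracket), overlap resolution, then rule 1 to fixpoint; the cycle
    # repeats until stable because a merge can itself unbalance brackets
    for (cycle in 1:10) {
      before_cycle <- m
      for (i in seq_len(nrow(m))) {
        repeat {
          fixed <- rule3_fix_unmatched_close(m[i, ], stext)
          if (fixed$start == m$start[i]) break
          trace <- rbind(trace, .trace_row(3L, fixed$doc_id, fixed$section,
                                           span_str(m[i, ]), span_str(fixed)))
          m[i, ] <- fixed
        }
        repeat {
          fixed <- rule4_fix_unmatched_open(m[i, ], stext)
          if (fixed$end == m$end[i]) break
          trace <- rbind(trace, .trace_row(4L, fixed$doc_id, fixed$section,
                                           span_str(m[i, ]), span_str(fixed)))
          m[i, ] <- fixed
        }
      }
      m <- .dedupe_overlaps(m)
      n_before <- nrow(m)
      m <- rule1_merge_chained(m, stext)
      if (nrow(m) < n_before) {
        trace <- rbind(trace, .trace_row(1L, m$doc_id[1], m$section[1],
                                         paste(n_before, "spans"),
                                         paste(nrow(m), "spans")))
      }
      if (identical(before_cycle$start, m$start) &&
          identical(before_cycle$end, m$end)) break
    }

    # rule 2 again: a merge can only join letter-bearing spans, but bracket
    # extension may have produced digit-only text in odd corners
    n_before <- nrow(m)
    m2 <- rule2_drop_numeric(m)
    if (nrow(m2) < n_before) {
      gone <- m[!grepl("[[:alpha:]]", m$text), , drop = FALSE]
      for (i in seq_len(nrow(gone))) {
        trace <- rbind(trace, .trace_row(2L, gone$doc_id[i], gone$section[i],
                                         span_str(gone[i, ]), "<removed>"))
      }
    }
    out <- rbind(out, m2)
  }
  rownames(out) <- NULL
  list(mentions = out, trace = trace)
}

#' Write a post-processing trace as TSV
#'
#' @param trace Trace frame from [apply_postprocess()].
#' @param path Output path.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
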