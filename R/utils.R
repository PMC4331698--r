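# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# The eight CHEMDNER entity classes, in the order used for reports.
ENTITY_TYPES <- c("ABBREVIATION", "FAMILY", "FORMULA", "IDENTIFIER",
                  "MULTIPLE", "SYSTEMATIC", "TRIVIAL", "NO_CLASS")

SECTION_LEVELS <- c("TITLE", "ABSTRACT")

# File section codes <-> canonical names.
section_from_code <- function(code) {
  out <- ifelse(code == "T", "TITLE", ifelse(code == "A", "ABSTRACT", NA_character_))
  if (anyNA(out)) stop("unknown section code: ", paste(unique(code[is.na(out)]), collapse = ", "))
  out
}

section_to_code <- function(section) {
  out <- ifelse(section == "TITLE", "T", ifelse(section == "ABSTRACT", "A", NA_character_))
  if (anyNA(out)) stop("unknown section: ", paste(unique(section[is.na(out)]), collapse = ", "))
  out
}

# 0-based half-open substring of a section text (vectorized over all
# arguments).
substr0 <- function(text, start, end) substring(text, start + 1L, end)

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Round half away from zero to `digits` decimals (R's round() is half-even;
# printed challenge tables use half-up).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

empty_mentions <- function() {
  data.frame(doc_id = character(), section = character(),
             start = integer(), end = integer(),
             text = character(), etype = character(),
             stringsAsFactors = FALSE)
}

as_mentions <- function(doc_id, section, start, end, text, etype) {
  data.frame(doc_id = as.character(doc_id), section = as.character(section),
             start = as.integer(start), end = as.integer(end),
             text = as.character(text), etype = as.character(etype),
             stringsAsFactors = FALSE)
}

# Check pairwise overlap among spans of one document-section.
check_no_overlap <- function(mentions, context = "mentions") {
  if (nrow(mentions) < 2) return(invisible(TRUE))
  key <- paste(mentions$doc_id, mentions$section)
  for (k in unique(key)) {
    m <- mentions[key == k, , drop = FALSE]
    m <- m[order(m$start, m$end), , drop = FALSE]
    if (nrow(m) > 1 && any(m$start[-1] < m$end[-nrow(m)])) {
      stop("overlapping ", context, " in document-section ", k)
    }
  }
  invisible(TRUE)
}
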