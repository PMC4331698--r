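# Micro precision / recall / F-measure over exact-span mention matching,
# mirroring the official challenge scoring semantics.

#' Match predicted against gold mentions
#'
#' A prediction counts as a true positive iff its (document, section, start,
#' end) quadruple -- and, in strict-typed mode, its entity type -- matches a
#' gold mention exactly. Counts are pooled over all documents (micro).
#' Duplicate identical predictions are deduplicated before matching, as
#' required of challenge submissions.
#'
#' @param gold Gold mention frame.
#' @param predicted Predicted mention frame.
#' @param typed If `TRUE`, the entity type must also match.
#' @return List with `tp`, `fp`, `fn`.
#' @export
match_mentions <- function(gold, predicted, typed = FALSE) {
  keyify <- function(m) {
    k <- paste(m$doc_id, m$section, m$start, m$end, sep = "\r")
    if (typed) k <- paste(k, m$etype, sep = "\r")
    k
  }
  gk <- unique(keyify(gold))
  pk <- unique(keyify(predicted))
  tp <- sum(pk %in% gk)
  list(tp = tp, fp = length(pk) - tp, fn = length(gk) - tp)
}

#' Micro metrics from confusion counts
#'
#' `P = tp / (tp + fp)`, `R = tp / (tp + fn)`, `F = 2PR / (P + R)`, reported
#' as percentages rounded half-up to two decimals. Zero denominators give 0.
#'
#' @param counts List with `tp`, `fp`, `fn` (from [match_mentions()]).
#' @return List with `precision`, `recall`, `f_measure` (percent), and the
#'   input counts.
#' @export
micro_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = round_half_up(100 * p),
       recall = round_half_up(100 * r),
       f_measure = round_half_up(100 * f),
       tp = tp, fp = fp, fn = fn)
}

#' F-measure from printed precision and recall percentages
#'
#' Harmonic mean on the percentage scale, rounded half-up to two decimals;
#' the form used to cross-check published result tables.
#'
#' @param precision,recall Percentages in `[0, 100]`.
#' @return F-measure percentage.
#' @export
f_from_pr <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 100, recall >= 0, recall <= 100)
  if (precision + recall == 0) return(0)
  round_half_up(2 * precision * recall / (precision + recall))
}

#' Evaluate a prediction set against gold mentions
#'
#' @param gold Gold mention frame.
#' @param predicted Predicted mention frame.
#' @param typed Strict-typed matching.
#' @return A `metric_report`: micro metrics plus per-document metrics.
#' @export
evaluate_mentions <- function(gold, predicted, typed = FALSE) {
  pooled <- micro_metrics(match_mentions(gold, predicted, typed = typed))
  docs <- sort(unique(c(gold$doc_id, predicted$doc_id)))
  per_doc <- do.call(rbind, lapply(docs, function(d) {
    m <- micro_metrics(match_mentions(gold[gold$doc_id == d, , drop = FALSE],
                                      predicted[predicted$doc_id == d, , drop = FALSE],
                                      typed = typed))
    data.frame(doc_id = d, precision = m$precision, recall = m$recall,
               f_measure = m$f_measure, tp = m$tp, fp = m$fp, fn = m$fn,
               stringsAsFactors = FALSE)
  }))
  structure(c(pooled, list(per_document = per_doc)), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("micro  P = %.2f  R = %.2f  F = %.2f   (tp %d, fp %d, fn %d)\n",
              x$precision, x$recall, x$f_measure, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Format several configurations as a result table
#'
#' @param reports Named list of `metric_report`s (one per configuration).
#' @return A data frame with one row per configuration: Precision, Recall,
#'   F-measure.
#' @export
metrics_table <- function(reports) {
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(configuration = nm, precision = r$precision, recall = r$recall,
               f_measure = r$f_measure, stringsAsFactors = FALSE)
  }))
}
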