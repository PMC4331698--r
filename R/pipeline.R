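# Document-level pipeline: preprocess -> features -> model -> BIO decode ->
# realign -> mentions, plus training-data preparation and the dev-set grid
# search helper.

#' Build labeled training sequences from documents and gold mentions
#'
#' Runs sentence splitting, tokenization and feature extraction over both
#' sections of every document and converts gold mention spans to per-token
#' BIO labels. Each sentence becomes one training sequence.
#'
#' @param documents Document frame ([read_abstracts()]).
#' @param mentions Gold mention frame ([read_annotations()]).
#' @param config A [feature_config()].
#' @param typed Emit typed BIO labels.
#' @return A list of sequences, each a list with `features` and `labels`.
#' @export
prepare_sequences <- function(documents, mentions, config = feature_config(),
                              typed = FALSE) {
  out <- list()
  for (r in seq_len(nrow(documents))) {
    for (section in SECTION_LEVELS) {
      text <- if (section == "TITLE") documents$title[r] else documents$abstract[r]
      toks <- tokenize_section(text, section)
      if (nrow(toks$tokens) == 0) next
      ment <- mentions[mentions$doc_id == documents$doc_id[r] &
                         mentions$section == section, , drop = FALSE]
      labels <- spans_to_bio(toks, ment, typed = typed)
      feats <- extract_features(toks, config)
      for (s in unique(toks$tokens$sentence_index)) {
        idx <- which(toks$tokens$sentence_index == s)
        out[[length(out) + 1L]] <- list(features = feats[idx],
                                        labels = labels[idx])
      }
    }
  }
  out
}

#' Train a chemical entity tagger on documents
#'
#' Convenience wrapper: [prepare_sequences()] then [train_crf()] or
#' [train_ssvm()] according to the training configuration.
#'
#' @param documents Document frame.
#' @param mentions Gold mention frame.
#' @param feature_cfg A [feature_config()].
#' @param train_cfg A [training_config()].
#' @return A trained [sequence_model()] carrying the feature configuration.
#' @export
train_tagger <- function(documents, mentions, feature_cfg = feature_config(),
                         train_cfg = training_config("CRF")) {
  data <- prepare_sequences(documents, mentions, feature_cfg,
                            typed = train_cfg$typed)
  model <- if (train_cfg$algorithm == "CRF") train_crf(data, train_cfg)
           else train_ssvm(data, train_cfg)
  model$feature_cfg <- feature_cfg
  model
}

# Confidence for one decoded mention.
# CRF: mean marginal posterior of the decoded labels over the mention's
# tokens. SSVM: logistic-squashed mean per-token flip margin (the score drop
# from switching one token's label to its best alternative).
mention_confidence <- function(algorithm, E, Trans, post, y, idx) {
  if (!is.null(post)) {
    mean(post[cbind(idx, y[idx])])
  } else {
    n <- nrow(E)
    margins <- vapply(idx, function(t) {
      local <- E[t, ]
      if (t > 1) local <- local + Trans[y[t - 1], ]
      if (t < n) local <- local + Trans[, y[t + 1]]
      local[y[t]] - max(local[-y[t]])
    }, numeric(1))
    stats::plogis(mean(margins))
  }
}

#' Tag documents with a trained model
#'
#' Full decode pipeline: preprocessing, feature extraction, per-sentence
#' Viterbi (with BIO structural masking), BIO-to-span conversion and offset
#' realignment against the original section text. Confidences come from
#' forward-backward marginals for CRF models and from logistic-squashed
#' score margins for SSVM models.
#'
#' @param model A trained [sequence_model()] (with `feature_cfg` attached,
#'   or pass `feature_cfg` explicitly).
#' @param documents Document frame.
#' @param feature_cfg Optional [feature_config()] override.
#' @param mask_illegal Apply the BIO structural mask at decode time.
#' @return A list with `mentions` (mention frame) and `scores` (confidence
#'   per mention, in `[0, 1]`).
#' @export
tag_documents <- function(model, documents, feature_cfg = NULL,
                          mask_illegal = TRUE) {
  if (is.null(feature_cfg)) feature_cfg <- model$feature_cfg
  if (is.null(feature_cfg)) feature_cfg <- feature_config()
  algorithm <- model$config$algorithm
  L <- length(model$labels)
  all_m <- empty_mentions()
  all_s <- numeric(0)
  for (r in seq_len(nrow(documents))) {
    for (section in SECTION_LEVELS) {
      text <- if (section == "TITLE") documents$title[r] else documents$abstract[r]
      toks <- tokenize_section(text, section)
      if (nrow(toks$tokens) == 0) next
      feats <- extract_features(toks, feature_cfg)
      fids_all <- feature_ids(feats, model$feature_index)
      labels <- character(nrow(toks$tokens))
      conf_ctx <- list()
      for (s in unique(toks$tokens$sentence_index)) {
        idx <- which(toks$tokens$sentence_index == s)
        E <- emission_matrix(fids_all[idx], model$W, L)
        mask <- if (mask_illegal) bio_mask(model$labels) else NULL
        y <- viterbi_mat(E, model$Trans, mask)
        labels[idx] <- model$labels[y]
        post <- if (identical(algorithm, "SSVM")) NULL
                else forward_backward_mat(E, model$Trans)$posteriors
        conf_ctx[[as.character(s)]] <- list(E = E, y = y, post = post, idx = idx)
      }
      toks <- realign(toks, text)  # verifies offset faithfulness
      ment <- bio_to_spans(toks, labels, doc_id = documents$doc_id[r])
      if (nrow(ment) == 0) next
      sc <- vapply(seq_len(nrow(ment)), function(i) {
        hit <- which(toks$tokens$end > ment$start[i] & toks$tokens$start < ment$end[i])
        s_id <- as.character(toks$tokens$sentence_index[hit[1]])
        ctx <- conf_ctx[[s_id]]
        local <- match(hit, ctx$idx)
        local <- local[!is.na(local)]
        mention_confidence(algorithm, ctx$E, model$Trans, ctx$post, ctx$y, local)
      }, numeric(1))
      all_m <- rbind(all_m, ment)
      all_s <- c(all_s, pmin(1, pmax(0, sc)))
    }
  }
  list(mentions = all_m, scores = all_s)
}

#' Grid search for regularization on a development set
#'
#' Trains on the training split for each candidate value and keeps the value
#' with the best micro F-measure on the development split (the train/dev
#' parameter-optimization protocol).
#'
#' @param train_docs,train_mentions Training split.
#' @param dev_docs,dev_mentions Development split.
#' @param algorithm `"CRF"` or `"SSVM"`.
#' @param grid Candidate values for `l2` (CRF) or `C` (SSVM).
#' @param feature_cfg A [feature_config()].
#' @param ... Passed to [training_config()].
#' @return List with `best` (the selected value), `scores` (dev F per
#'   candidate) and `model` (refit with the selected value).
#' @export
grid_search <- function(train_docs, train_mentions, dev_docs, dev_mentions,
                        algorithm = "CRF", grid = c(0.1, 1, 10),
                        feature_cfg = feature_config(), ...) {
  scores <- numeric(length(grid))
  models <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cfg <- if (algorithm == "CRF") training_config("CRF", l2 = grid[i], ...)
           else training_config("SSVM", C = grid[i], ...)
    models[[i]] <- train_tagger(train_docs, train_mentions, feature_cfg, cfg)
    pred <- tag_documents(models[[i]], dev_docs)
    rep <- micro_metrics(match_mentions(dev_mentions, pred$mentions))
    scores[i] <- rep$f_measure
  }
  best <- which.max(scores)
  list(best = grid[best], scores = stats::setNames(scores, grid),
       model = models[[best]])
}
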