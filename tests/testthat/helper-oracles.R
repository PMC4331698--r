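# Shared fixtures and independent oracles for the test suite.

# Small random model over a toy feature alphabet.
random_toy_model <- function(n_feats = 5, labels = c("B", "I", "O")) {
  fi <- stats::setNames(seq_len(n_feats), paste0("f", seq_len(n_feats)))
  sequence_model(labels, fi,
                 W = matrix(stats::rnorm(n_feats * length(labels)), n_feats),
                 Trans = matrix(stats::rnorm(length(labels)^2), length(labels)))
}

random_toy_features <- function(n, feat_names) {
  lapply(seq_len(n), function(t) sample(feat_names, sample(seq_along(feat_names), 1)))
}

# Brute-force oracle: score every labeling of a sequence.
enumerate_scores <- function(model, features) {
  n <- length(features)
  L <- length(model$labels)
  grid <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))
  scores <- apply(grid, 1, function(y) score_sequence(model, features, model$labels[y]))
  list(grid = grid, scores = scores)
}

# Brute-force average mutual information of a hard clustering, from raw
# adjacent-pair counts of a token-id corpus.
brute_mi <- function(ids, assign) {
  from <- integer(0); to <- integer(0)
  for (s in ids) if (length(s) >= 2) {
    from <- c(from, assign[s[-length(s)]]); to <- c(to, assign[s[-1]])
  }
  tab <- table(from, to)
  p <- tab / sum(tab)
  pl <- rowSums(p); pr <- colSums(p)
  total <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) total <- total + p[i, j] * log(p[i, j] / (pl[i] * pr[j]))
  }
  total
}

# A tiny deterministic labeled corpus where one feature ("chem") perfectly
# identifies entity tokens: linearly separable for both learners.
separable_toy_data <- function(n_seq = 20, seed = 99) {
  chemner:::with_seed(seed, {
    lapply(seq_len(n_seq), function(s) {
      n <- sample(3:6, 1)
      is_chem <- stats::runif(n) < 0.3
      feats <- lapply(seq_len(n), function(t) {
        if (is_chem[t]) c("chem", paste0("w", sample(5, 1)))
        else c("plain", paste0("w", sample(5, 1)))
      })
      labels <- ifelse(is_chem, "B", "O")
      list(features = feats, labels = labels)
    })
  })
}

# Tiny document set used across io/pipeline tests.
tiny_documents <- function() {
  data.frame(doc_id = c("D1", "D2"),
             title = c("Aspirin works.", "A study of NaCl."),
             abstract = c("We gave aspirin daily.", "Salt NaCl was measured."),
             stringsAsFactors = FALSE)
}
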