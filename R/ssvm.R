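# Structured SVM training: margin-rescaled structured hinge loss minimized
# by averaged stochastic subgradient descent with seeded shuffling.

# Structured hinge objective 0.5*lambda*||w||^2 + mean per-sequence
# max-violation, at given weights, over an encoded corpus.
ssvm_objective <- function(W, Tr, enc, lambda, cost = 1) {
  L <- length(enc$labels)
  total <- 0
  for (s in seq_along(enc$ns)) {
    idx <- enc$starts[s]:enc$ends[s]
    fids <- enc$fids[[s]]
    ys <- enc$y[idx]
    n <- length(idx)
    E <- emission_matrix(fids, W, L)
    aug <- matrix(cost, n, L)
    aug[cbind(seq_len(n), ys)] <- 0
    yhat <- viterbi_mat(E + aug, Tr)
    s_hat <- sum(E[cbind(seq_len(n), yhat)]) + sum(aug[cbind(seq_len(n), yhat)])
    s_gold <- sum(E[cbind(seq_len(n), ys)])
    if (n > 1) {
      s_hat <- s_hat + sum(Tr[cbind(yhat[-n], yhat[-1])])
      s_gold <- s_gold + sum(Tr[cbind(ys[-n], ys[-1])])
    }
    total <- total + max(0, s_hat - s_gold)
  }
  0.5 * lambda * (sum(W^2) + sum(Tr^2)) + total / length(enc$ns)
}

#' Train a structured SVM sequence labeler
#'
#' Minimizes the margin-rescaled structured hinge objective
#' `0.5 * lambda * ||w||^2 + (1/N) * sum_s max_y [Hamming(y, y_s) +
#' score(y) - score(y_s)]_+` with `lambda = 1 / (C * N)`, by stochastic
#' subgradient descent: per sequence, the most violating labeling is found
#' by [loss_augmented_viterbi()] and the weights move toward the gold
#' feature counts and away from the violator's, after L2 shrinkage. Epoch
#' order is shuffled under the configured seed, and the returned weights are
#' the average of the per-epoch snapshots, which stabilizes the final model.
#'
#' @param data List of labeled sequences (see [crf_loss_grad()]).
#' @param config A [training_config()] with `algorithm = "SSVM"`.
#' @return A trained [sequence_model()]; `config$objective_trace` records
#'   the hinge objective after each epoch.
#' @export
train_ssvm <- function(data, config = training_config("SSVM")) {
  labels <- label_set(config$typed)
  enc <- encode_corpus(data, labels)
  L <- length(labels); F_ <- length(enc$feature_index)
  N <- length(enc$ns)
  lambda <- 1 / (config$C * N)
  # W is stored as scale * W_raw so the per-update L2 shrinkage is a scalar
  # multiplication instead of a full dense-matrix rescale.
  W_raw <- matrix(0, F_, L)
  scale <- 1
  Tr <- matrix(0, L, L)
  W_sum <- W_raw; Tr_sum <- Tr
  trace <- numeric(config$epochs)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      eta <- config$lr / (1 + (ep - 1) / config$epochs)
      for (s in sample.int(N)) {
        idx <- enc$starts[s]:enc$ends[s]
        fids <- enc$fids[[s]]
        ys <- enc$y[idx]
        n <- length(idx)
        E <- emission_matrix(fids, W_raw, L) * scale
        aug <- matrix(1, n, L)
        aug[cbind(seq_len(n), ys)] <- 0
        yhat <- viterbi_mat(E + aug, Tr)
        s_hat <- sum(E[cbind(seq_len(n), yhat)]) + sum(aug[cbind(seq_len(n), yhat)])
        s_gold <- sum(E[cbind(seq_len(n), ys)])
        if (n > 1) {
          s_hat <- s_hat + sum(Tr[cbind(yhat[-n], yhat[-1])])
          s_gold <- s_gold + sum(Tr[cbind(ys[-n], ys[-1])])
        }
        shrink <- 1 - eta * lambda
        scale <- scale * shrink
        Tr <- Tr * shrink
        if (s_hat - s_gold > 0) {
          for (t in seq_len(n)) {
            if (yhat[t] != ys[t]) {
              f <- fids[[t]]
              if (length(f)) {
                W_raw[f, ys[t]] <- W_raw[f, ys[t]] + eta / scale
                W_raw[f, yhat[t]] <- W_raw[f, yhat[t]] - eta / scale
              }
            }
          }
          if (n > 1) {
            for (t in 2:n) {
              Tr[ys[t - 1], ys[t]] <- Tr[ys[t - 1], ys[t]] + eta
              Tr[yhat[t - 1], yhat[t]] <- Tr[yhat[t - 1], yhat[t]] - eta
            }
          }
        }
      }
      W_sum <- W_sum + W_raw * scale
      Tr_sum <- Tr_sum + Tr
      trace[ep] <- ssvm_objective(W_raw * scale, Tr, enc, lambda)
      if (!is.finite(trace[ep])) stop("non-finite SSVM objective")
    }
  })
  W_avg <- W_sum / config$epochs
  Tr_avg <- Tr_sum / config$epochs
  sequence_model(labels, enc$feature_index, W = W_avg, Trans = Tr_avg,
                 config = c(unclass(config), list(objective_trace = trace)))
}
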