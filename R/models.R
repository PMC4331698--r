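# Linear-chain sequence model shared by the CRF and SSVM trainers: a label
# set, a feature-name index, per-label emission weights and label-transition
# weights, with Viterbi and forward-backward inference.

#' Construct a linear-chain sequence model
#'
#' @param labels Character label set (order fixes Viterbi tie-breaking;
#'   default `B < I < O`).
#' @param feature_index Named integer vector mapping feature names to
#'   columns of the emission weight matrix.
#' @param W Emission weight matrix, `length(feature_index)` x
#'   `length(labels)`.
#' @param Trans Transition weight matrix, `length(labels)` squared
#'   (`Trans[i, j]` scores label `i` followed by label `j`).
#' @param config Training configuration list (algorithm, hyperparameters,
#'   seed); kept as metadata.
#' @return A `sequence_model`.
#' @export
sequence_model <- function(labels = c("B", "I", "O"),
                           feature_index = integer(0),
                           W = NULL, Trans = NULL, config = list()) {
  L <- length(labels)
  F_ <- length(feature_index)
  if (is.null(W)) W <- matrix(0, F_, L)
  if (is.null(Trans)) Trans <- matrix(0, L, L)
  stopifnot(nrow(W) == F_, ncol(W) == L, all(dim(Trans) == c(L, L)),
            all(is.finite(W)), all(is.finite(Trans)))
  if (F_ > 0 && anyDuplicated(names(feature_index))) stop("feature index not injective")
  structure(list(labels = labels, feature_index = feature_index,
                 W = W, Trans = Trans, config = config),
            class = "sequence_model")
}

#' @export
print.sequence_model <- function(x, ...) {
  cat("<sequence_model> ", length(x$labels), " labels, ",
      length(x$feature_index), " features",
      if (!is.null(x$config$algorithm)) paste0(", trained by ", x$config$algorithm),
      "\n", sep = "")
  invisible(x)
}

# Feature-name lists -> integer id lists under a model's index (unknown
# features are dropped). One match() over the flattened input, so the index
# is hashed once per call -- callers should batch as many tokens as
# possible into a single invocation.
feature_ids <- function(features, feature_index) {
  lens <- lengths(features)
  flat <- unlist(features, use.names = FALSE)
  ids <- unname(feature_index[match(flat, names(feature_index))])
  grp <- rep.int(seq_along(features), lens)
  keep <- !is.na(ids)
  out <- rep(list(integer(0)), length(features))
  if (any(keep)) {
    found <- split(ids[keep], grp[keep])
    out[as.integer(names(found))] <- found
  }
  out
}

# Emission score matrix (n x L) for one sequence given id lists.
emission_matrix <- function(fids, W, L) {
  n <- length(fids)
  E <- matrix(0, n, L)
  for (t in seq_len(n)) {
    if (length(fids[[t]])) E[t, ] <- colSums(W[fids[[t]], , drop = FALSE])
  }
  E
}

# Decode-time structural mask: -Inf where a transition (or start label) is
# illegal under the BIO grammar -- I may not start a sequence, O may not
# precede I, and a typed I must continue the same type.
bio_mask <- function(labels) {
  L <- length(labels)
  base <- sub("-.*$", "", labels)
  type <- ifelse(grepl("-", labels, fixed = TRUE), sub("^[BI]-", "", labels), "")
  start_ok <- base != "I"
  trans_ok <- matrix(TRUE, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (base[j] == "I") {
      if (base[i] == "O") trans_ok[i, j] <- FALSE
      else if (type[j] != "" && type[i] != type[j]) trans_ok[i, j] <- FALSE
    }
  }
  list(start = ifelse(start_ok, 0, -Inf),
       trans = ifelse(trans_ok, 0, -Inf))
}

#' Score a labeling of a sequence
#'
#' Sum over positions of the emission weights active at each (token, label)
#' plus the transition weight of each adjacent label pair.
#'
#' @param model A [sequence_model()].
#' @param features List of per-token feature-name vectors.
#' @param labels Character labels, one per token.
#' @return A numeric score.
#' @export
score_sequence <- function(model, features, labels) {
  stopifnot(length(features) == length(labels))
  y <- match(labels, model$labels)
  if (anyNA(y)) stop("unknown label: ", labels[is.na(y)][1])
  if (length(y) == 0) return(0)
  fids <- feature_ids(features, model$feature_index)
  E <- emission_matrix(fids, model$W, length(model$labels))
  s <- sum(E[cbind(seq_along(y), y)])
  if (length(y) > 1) s <- s + sum(model$Trans[cbind(y[-length(y)], y[-1])])
  s
}

# Core Viterbi on an emission matrix. Ties break toward the smallest label
# index. `mask` is a list(start, trans) of 0/-Inf additive penalties.
viterbi_mat <- function(E, Trans, mask = NULL) {
  n <- nrow(E); L <- ncol(E)
  if (n == 0) return(integer(0))
  delta <- matrix(-Inf, n, L)
  back <- matrix(0L, n, L)
  start_pen <- if (is.null(mask)) rep(0, L) else mask$start
  trans_pen <- if (is.null(mask)) matrix(0, L, L) else mask$trans
  delta[1, ] <- E[1, ] + start_pen
  if (n > 1) {
    Tp <- Trans + trans_pen
    for (t in 2:n) {
      cand <- delta[t - 1, ] + Tp          # L x L: cand[i, j]
      best <- apply(cand, 2, which.max)    # first max = smallest label index
      delta[t, ] <- cand[cbind(best, seq_len(L))] + E[t, ]
      back[t, ] <- best
    }
  }
  y <- integer(n)
  y[n] <- which.max(delta[n, ])
  if (n > 1) for (t in n:2) y[t - 1] <- back[t, y[t]]
  y
}

#' Viterbi decoding
#'
#' Returns an argmax labeling of [score_sequence()]. Ties break by label
#' order. When `mask_illegal` is on (the default), sequences violating the
#' BIO grammar (an `I` at sequence start or after `O`) are excluded
#' structurally.
#'
#' @param model A [sequence_model()].
#' @param features List of per-token feature-name vectors.
#' @param mask_illegal Apply the BIO structural mask at decode time.
#' @return Character labels, one per token (empty input gives an empty
#'   vector).
#' @export
viterbi <- function(model, features, mask_illegal = TRUE) {
  if (length(features) == 0) return(character(0))
  fids <- feature_ids(features, model$feature_index)
  E <- emission_matrix(fids, model$W, length(model$labels))
  mask <- if (mask_illegal) bio_mask(model$labels) else NULL
  model$labels[viterbi_mat(E, model$Trans, mask)]
}

# log(sum(exp(x))) guarded against -Inf-only rows.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Core forward-backward on an emission matrix: log-partition, per-position
# posteriors, log alpha/beta tables.
forward_backward_mat <- function(E, Trans) {
  n <- nrow(E); L <- ncol(E)
  alpha <- matrix(-Inf, n, L)
  beta <- matrix(-Inf, n, L)
  alpha[1, ] <- E[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (j in seq_len(L)) alpha[t, j] <- logsumexp(alpha[t - 1, ] + Trans[, j]) + E[t, j]
    }
  }
  beta[n, ] <- 0
  if (n > 1) {
    for (t in (n - 1):1) {
      for (i in seq_len(L)) beta[t, i] <- logsumexp(Trans[i, ] + E[t + 1, ] + beta[t + 1, ])
    }
  }
  logZ <- logsumexp(alpha[n, ])
  post <- exp(alpha + beta - logZ)
  post <- post / rowSums(post)
  list(logZ = logZ, posteriors = post, alpha = alpha, beta = beta)
}

#' Forward-backward inference
#'
#' Computes the log-partition function (log-sum-exp of all sequence scores)
#' and per-position label posteriors, in log space.
#'
#' @param model A [sequence_model()].
#' @param features List of per-token feature-name vectors.
#' @return List with `logZ` and `posteriors` (n x L, rows sum to 1).
#' @export
forward_backward <- function(model, features) {
  stopifnot(length(features) > 0)
  fids <- feature_ids(features, model$feature_index)
  E <- emission_matrix(fids, model$W, length(model$labels))
  fb <- forward_backward_mat(E, model$Trans)
  colnames(fb$posteriors) <- model$labels
  list(logZ = fb$logZ, posteriors = fb$posteriors)
}

#' Loss-augmented Viterbi
#'
#' Argmax of sequence score plus Hamming distance to the gold labeling; the
#' per-position loss is folded into the emissions so ordinary Viterbi
#' applies. With `cost = 0` this reduces to [viterbi()] without masking.
#'
#' @param model A [sequence_model()].
#' @param features List of per-token feature-name vectors.
#' @param gold Gold labels, one per token.
#' @param cost Per-position cost added for labels differing from gold.
#' @return Character labels.
#' @export
loss_augmented_viterbi <- function(model, features, gold, cost = 1) {
  stopifnot(length(features) == length(gold))
  if (length(gold) == 0) return(character(0))
  y <- match(gold, model$labels)
  if (anyNA(y)) stop("unknown gold label")
  fids <- feature_ids(features, model$feature_index)
  L <- length(model$labels)
  E <- emission_matrix(fids, model$W, L)
  aug <- matrix(cost, length(gold), L)
  aug[cbind(seq_along(y), y)] <- 0
  model$labels[viterbi_mat(E + aug, model$Trans)]
}

#' Save / load a trained sequence model
#'
#' A versioned single-file archive of the label set, feature index, weight
#' matrices and training configuration; `load_model(save_model(m))` is
#' identical to `m`.
#'
#' @param model A [sequence_model()].
#' @param path File path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "chemner-model", version = 1L,
               labels = model$labels, feature_index = model$feature_index,
               W = model$W, Trans = model$Trans, config = model$config),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "chemner-model")) stop("not a chemner model file")
  sequence_model(x$labels, x$feature_index, x$W, x$Trans, x$config)
}
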