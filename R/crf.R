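# Conditional random field training: regularized maximum likelihood by
# L-BFGS over the shared linear-chain parameterization.

#' Training configuration
#'
#' @param algorithm `"CRF"` or `"SSVM"`.
#' @param l2 L2 regularization strength for CRF (> 0 recommended).
#' @param C SSVM regularization trade-off (> 0).
#' @param epochs SSVM training epochs.
#' @param lr SSVM subgradient step size.
#' @param tol Relative convergence tolerance for L-BFGS.
#' @param maxit Maximum L-BFGS iterations.
#' @param typed Use the typed label alphabet (one B/I pair per entity type).
#' @param seed Integer seed (SSVM shuffling).
#' @return A `training_config` list.
#' @export
training_config <- function(algorithm = c("CRF", "SSVM"), l2 = 1.0, C = 0.1,
                            epochs = 10L, lr = 0.1, tol = 1e-6, maxit = 200L,
                            typed = FALSE, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(l2 >= 0, C > 0, epochs >= 1, lr > 0, tol > 0)
  structure(list(algorithm = algorithm, l2 = l2, C = C,
                 epochs = as.integer(epochs), lr = lr, tol = tol,
                 maxit = as.integer(maxit), typed = isTRUE(typed),
                 seed = as.integer(seed)),
            class = "training_config")
}

# Encode labeled sequences (list of list(features, labels)) against a label
# set: feature index (sorted names for determinism), sparse design matrix,
# integer labels, sequence boundaries.
encode_corpus <- function(data, labels, feature_index = NULL) {
  stopifnot(length(data) > 0)
  feats <- lapply(data, `[[`, "features")
  labs <- lapply(data, `[[`, "labels")
  if (is.null(feature_index)) {
    nm <- sort(unique(unlist(feats, use.names = FALSE)))
    feature_index <- stats::setNames(seq_along(nm), nm)
  }
  # one flattened lookup for the whole corpus, re-split per sequence
  all_tok_feats <- unlist(feats, recursive = FALSE, use.names = FALSE)
  all_fids <- feature_ids(all_tok_feats, feature_index)
  fids <- split(all_fids, factor(rep.int(seq_along(feats),
                                         vapply(feats, length, integer(1))),
                                 levels = seq_along(feats)))
  names(fids) <- NULL
  y <- match(unlist(labs, use.names = FALSE), labels)
  if (anyNA(y)) stop("label outside the configured alphabet")
  ns <- vapply(feats, length, integer(1))
  tok_i <- unlist(lapply(unlist(fids, recursive = FALSE), length))
  flat_fids <- unlist(fids, use.names = FALSE)
  row_idx <- rep.int(seq_len(sum(ns)), tok_i)
  X <- Matrix::sparseMatrix(i = row_idx, j = flat_fids, x = 1,
                            dims = c(sum(ns), length(feature_index)))
  ends <- cumsum(ns)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  # empirical transition counts
  L <- length(labels)
  transN <- matrix(0, L, L)
  off <- 0L
  for (s in seq_along(ns)) {
    if (ns[s] > 1) {
      ys <- y[(off + 1L):(off + ns[s])]
      for (t in 2:ns[s]) transN[ys[t - 1], ys[t]] <- transN[ys[t - 1], ys[t]] + 1
    }
    off <- off + ns[s]
  }
  list(X = X, y = y, starts = starts, ends = ends, ns = ns,
       feature_index = feature_index, labels = labels, fids = fids,
       transN = transN)
}

# Column/row log-sum-exp of a small matrix.
lse_cols <- function(M) {
  mx <- apply(M, 2, max)
  ok <- is.finite(mx)
  out <- mx
  if (any(ok)) out[ok] <- mx[ok] + log(colSums(exp(sweep(M[, ok, drop = FALSE], 2, mx[ok]))))
  out
}
lse_rows <- function(M) lse_cols(t(M))

# Row-wise log-sum-exp of an n x L matrix, vectorized over rows.
lse_rowwise <- function(M) {
  mx <- M[, 1]
  for (j in 2:ncol(M)) mx <- pmax(mx, M[, j])
  acc <- exp(M[, 1] - mx)
  for (j in 2:ncol(M)) acc <- acc + exp(M[, j] - mx)
  mx + log(acc)
}

# Negative log-likelihood and gradient over an encoded corpus at packed
# parameters c(vec(W), vec(Trans)). The forward and backward recursions run
# lock-step across all sequences (one vectorized step per position), so the
# cost per L-BFGS evaluation is O(max_len) vector operations rather than
# O(total_tokens) interpreted-loop iterations.
crf_objective <- function(par, enc, l2) {
  L <- length(enc$labels)
  F_ <- length(enc$feature_index)
  W <- matrix(par[seq_len(F_ * L)], F_, L)
  Tr <- matrix(par[F_ * L + seq_len(L * L)], L, L)
  E_all <- as.matrix(enc$X %*% W)
  n_tok <- nrow(E_all)
  S <- length(enc$ns)
  max_n <- max(enc$ns)
  A <- matrix(-Inf, n_tok, L)   # log alpha per token
  Bt <- matrix(-Inf, n_tok, L)  # log beta per token
  # forward, all sequences in lock step
  act1 <- enc$starts
  A[act1, ] <- E_all[act1, , drop = FALSE]
  if (max_n > 1) for (t in 2:max_n) {
    live <- which(enc$ns >= t)
    if (!length(live)) break
    rows <- enc$starts[live] + (t - 1L)
    prev <- A[rows - 1L, , drop = FALSE]
    nxt <- matrix(0, length(live), L)
    for (j in seq_len(L)) {
      nxt[, j] <- lse_rowwise(sweep(prev, 2, Tr[, j], "+"))
    }
    A[rows, ] <- nxt + E_all[rows, , drop = FALSE]
  }
  # backward
  Bt[enc$ends, ] <- 0
  if (max_n > 1) for (t in (max_n - 1):1) {
    live <- which(enc$ns > t)
    if (!length(live)) next
    rows <- enc$starts[live] + (t - 1L)
    nxt_rows <- rows + 1L
    EB <- E_all[nxt_rows, , drop = FALSE] + Bt[nxt_rows, , drop = FALSE]
    cur <- matrix(0, length(live), L)
    for (i in seq_len(L)) {
      cur[, i] <- lse_rowwise(sweep(EB, 2, Tr[i, ], "+"))
    }
    Bt[rows, ] <- cur
  }
  logZ <- lse_rowwise(A[enc$ends, , drop = FALSE])
  # loss: sum logZ minus gold scores
  gold_emit <- sum(E_all[cbind(seq_len(n_tok), enc$y)])
  gold <- gold_emit + sum(Tr * enc$transN)
  loss <- sum(logZ) - gold
  # posteriors
  logZ_tok <- rep.int(logZ, enc$ns)
  P_all <- exp(A + Bt - logZ_tok)
  P_all <- P_all / rowSums(P_all)
  # expected transition counts, vectorized per (i, j) over all positions
  gradT <- matrix(0, L, L)
  mid <- setdiff(seq_len(n_tok), enc$starts)  # every non-initial position
  if (length(mid)) {
    for (i in seq_len(L)) for (j in seq_len(L)) {
      gradT[i, j] <- sum(exp(A[mid - 1L, i] + Tr[i, j] + E_all[mid, j] +
                               Bt[mid, j] - logZ_tok[mid]))
    }
  }
  Y <- matrix(0, n_tok, L)
  Y[cbind(seq_len(n_tok), enc$y)] <- 1
  gradW <- as.matrix(Matrix::crossprod(enc$X, P_all - Y))
  gradT <- gradT - enc$transN
  grad <- c(as.numeric(gradW), as.numeric(gradT))
  loss <- loss + 0.5 * l2 * sum(par^2)
  grad <- grad + l2 * par
  if (!is.finite(loss)) stop("non-finite CRF loss")
  list(loss = loss, grad = grad)
}

#' CRF loss and gradient
#'
#' Negative conditional log-likelihood of a batch of labeled sequences plus
#' an L2 penalty `0.5 * l2 * ||w||^2`, with its exact gradient (expected
#' minus empirical feature counts plus the penalty gradient). Evaluated at
#' the weights stored in `model`.
#'
#' @param model A [sequence_model()].
#' @param data List of sequences, each a list with `features` (list of
#'   per-token feature-name vectors) and `labels`.
#' @param l2 L2 strength.
#' @return List with `loss` and `grad` (list with `W` and `Trans` matrices).
#' @export
crf_loss_grad <- function(model, data, l2 = 0) {
  enc <- encode_corpus(data, model$labels, feature_index = model$feature_index)
  L <- length(model$labels); F_ <- length(model$feature_index)
  par <- c(as.numeric(model$W), as.numeric(model$Trans))
  obj <- crf_objective(par, enc, l2)
  list(loss = obj$loss,
       grad = list(W = matrix(obj$grad[seq_len(F_ * L)], F_, L),
                   Trans = matrix(obj$grad[F_ * L + seq_len(L * L)], L, L)))
}

#' Train a CRF sequence labeler
#'
#' L-BFGS minimization of the regularized negative log-likelihood from a
#' zero start. Deterministic given the data order and configuration.
#'
#' @param data List of labeled sequences (see [crf_loss_grad()]).
#' @param config A [training_config()] with `algorithm = "CRF"`.
#' @return A trained [sequence_model()].
#' @export
train_crf <- function(data, config = training_config("CRF")) {
  labels <- label_set(config$typed)
  enc <- encode_corpus(data, labels)
  L <- length(labels); F_ <- length(enc$feature_index)
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    key <- par
    if (!is.null(cache$par) && identical(cache$par, key)) return(cache$obj)
    obj <- crf_objective(par, enc, config$l2)
    cache$par <- key
    cache$obj <- obj
    obj
  }
  fn <- function(par) evaluate(par)$loss
  gr <- function(par) evaluate(par)$grad
  fit <- stats::optim(rep(0, F_ * L + L * L), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = config$maxit,
                                     factr = config$tol / .Machine$double.eps))
  par <- fit$par
  if (any(!is.finite(par))) stop("CRF training produced non-finite weights")
  sequence_model(labels, enc$feature_index,
                 W = matrix(par[seq_len(F_ * L)], F_, L),
                 Trans = matrix(par[F_ * L + seq_len(L * L)], L, L),
                 config = c(unclass(config), list(converged = fit$convergence == 0)))
}
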