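# Unsupervised word representations trained on unlabeled text, exposed as
# discrete per-word features: Brown clustering (bit-path prefixes), random
# indexing and skip-gram embeddings (k-means cluster ids).

#' Build a vocabulary from tokenized text
#'
#' @param corpus Character vector of sentences (whitespace-tokenized, one
#'   sentence per element), or a list of token character vectors.
#' @param min_count Words seen fewer than `min_count` times are pooled into
#'   the `<unk>` entry.
#' @return A `vocab` list: `word` (character, `<unk>` last when present),
#'   `freq` (integer), `index` (named integer, 1-based).
#' @export
build_vocab <- function(corpus, min_count = 1L) {
  toks <- corpus_tokens(corpus)
  all_tok <- unlist(toks, use.names = FALSE)
  if (length(all_tok) == 0) stop("empty corpus")
  tab <- table(all_tok)
  freq <- as.integer(tab)
  words <- names(tab)
  keep <- freq >= min_count
  unk_count <- sum(freq[!keep])
  words_kept <- words[keep]
  freq_kept <- freq[keep]
  ord <- order(-freq_kept, words_kept)
  words_kept <- words_kept[ord]
  freq_kept <- freq_kept[ord]
  if (unk_count > 0 || !all(keep)) {
    words_kept <- c(words_kept, "<unk>")
    freq_kept <- c(freq_kept, as.integer(unk_count))
  }
  structure(list(word = words_kept, freq = freq_kept,
                 index = stats::setNames(seq_along(words_kept), words_kept)),
            class = "vocab")
}

# Normalize corpus input to a list of token vectors.
corpus_tokens <- function(corpus) {
  if (is.list(corpus)) return(corpus)
  strsplit(corpus[nzchar(corpus)], "[[:space:]]+")
}

# Map sentences to integer id sequences under a vocabulary (<unk> fallback).
corpus_ids <- function(corpus, vocab) {
  unk <- if ("<unk>" %in% names(vocab$index)) vocab$index[["<unk>"]] else NA_integer_
  lapply(corpus_tokens(corpus), function(tk) {
    ids <- unname(vocab$index[tk])
    ids[is.na(ids)] <- unk
    ids[!is.na(ids)]
  })
}

# Bigram count matrix over adjacent within-sentence word pairs.
bigram_counts <- function(ids, V) {
  from <- integer(0); to <- integer(0)
  for (s in ids) {
    if (length(s) >= 2) {
      from <- c(from, s[-length(s)])
      to <- c(to, s[-1])
    }
  }
  if (length(from) == 0) stop("corpus has no adjacent word pairs")
  Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(V, V))
}

# x * log(x / d) with the 0 log 0 = 0 convention.
xlogx_ratio <- function(x, d) {
  out <- x
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos] / d[pos])
  out[!pos] <- 0
  out
}

# Average mutual information of a cluster bigram probability matrix.
cluster_mi <- function(p) {
  pl <- rowSums(p); pr <- colSums(p)
  d <- outer(pl, pr)
  sum(xlogx_ratio(p, d))
}

#' Train a Brown clustering model
#'
#' Greedy agglomerative merging that maximizes the average mutual
#' information between adjacent-word cluster bigrams, using the classic
#' frequency-sorted merge window: the `n_clusters` most frequent words start
#' as singleton clusters, each remaining word is added in frequency order
#' and the pair of active clusters whose merge loses the least mutual
#' information is merged; finally the surviving clusters are merged down to
#' one, yielding a binary tree whose leaf bit-paths encode the words. Ties
#' break on the smallest contained word id, which makes training fully
#' deterministic.
#'
#' @param corpus Sentences (see [build_vocab()]).
#' @param vocab A [build_vocab()] result.
#' @param n_clusters Size of the active merge window (the cluster count at
#'   which the tree's top level is formed). Must not exceed the vocabulary
#'   size.
#' @return A `brown_model` list: `paths` (named character, word to bit
#'   path), `merges` (data frame of merge steps), `n_clusters`.
#' @export
train_brown <- function(corpus, vocab, n_clusters = 100L) {
  V <- length(vocab$word)
  if (n_clusters > V) stop("n_clusters (", n_clusters, ") exceeds vocabulary size (", V, ")")
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  ids <- corpus_ids(corpus, vocab)
  B <- bigram_counts(ids, V)
  total <- sum(B)

  # word order: frequency descending, then word id ascending
  ord <- order(-vocab$freq, seq_len(V))
  C <- min(n_clusters, V)
  active_words <- ord[seq_len(C)]          # word id of each active cluster seed
  members <- lapply(active_words, function(w) w)
  reps <- active_words                     # smallest word id per cluster
  paths <- stats::setNames(rep("", V), vocab$word)
  merges <- list()

  # cluster-level bigram counts among active words
  memb_vec <- integer(V)                   # word -> active cluster slot (0 = inactive)
  memb_vec[active_words] <- seq_len(C)
  act <- which(memb_vec > 0)
  Bd <- as.matrix(B[act, act, drop = FALSE])
  N <- matrix(0, C, C)
  slot <- memb_vec[act]
  for (i in seq_along(act)) for (j in seq_along(act)) {
    N[slot[i], slot[j]] <- N[slot[i], slot[j]] + Bd[i, j]
  }

  merge_pair <- function(a, b) {
    # merge cluster slots a, b (a kept); record bits
    bit_a <- if (reps[a] <= reps[b]) "0" else "1"
    bit_b <- if (bit_a == "0") "1" else "0"
    wa <- vocab$word[members[[a]]]; wb <- vocab$word[members[[b]]]
    paths[wa] <<- paste0(bit_a, paths[wa])
    paths[wb] <<- paste0(bit_b, paths[wb])
    merges[[length(merges) + 1L]] <<- data.frame(rep_kept = reps[a], rep_gone = reps[b])
    members[[a]] <<- c(members[[a]], members[[b]])
    reps[a] <<- min(reps[a], reps[b])
    N[a, ] <<- N[a, ] + N[b, ]
    N[, a] <<- N[, a] + N[, b]
    # drop slot b
    keep <- setdiff(seq_len(nrow(N)), b)
    N <<- N[keep, keep, drop = FALSE]
    members <<- members[keep]
    reps <<- reps[keep]
  }

  best_merge <- function() {
    C_now <- nrow(N)
    p <- N / total
    pl <- rowSums(p); pr <- colSums(p)
    q <- xlogx_ratio(p, outer(pl, pr))
    S <- rowSums(q) + colSums(q) - diag(q)
    best <- list(score = -Inf, a = 0L, b = 0L)
    for (a in seq_len(C_now - 1L)) {
      bs <- (a + 1L):C_now
      # row contributions of merged cluster m against all k
      R <- p[bs, , drop = FALSE] + matrix(p[a, ], length(bs), C_now, byrow = TRUE)
      denR <- outer(pl[a] + pl[bs], pr)
      qR <- xlogx_ratio(R, denR)
      # column contributions k -> m
      Cc <- p[, bs, drop = FALSE] + matrix(p[, a], C_now, length(bs))
      denC <- outer(pl, pr[a] + pr[bs])
      qC <- xlogx_ratio(Cc, denC)
      # exclude k in {a, b} from the cross sums; add the m->m self term
      pmm <- p[a, a] + p[a, bs] + p[bs, a] + diag(p)[bs]
      dmm <- (pl[a] + pl[bs]) * (pr[a] + pr[bs])
      qmm <- xlogx_ratio(pmm, dmm)
      rs <- rowSums(qR) - qR[, a] - qR[cbind(seq_along(bs), bs)]
      cs <- colSums(qC) - qC[a, ] - qC[cbind(bs, seq_along(bs))]
      delta <- -S[a] - S[bs] + q[a, bs] + q[bs, a] + rs + cs + qmm
      mx <- max(delta)
      if (mx > best$score + 1e-12 ||
          (mx >= best$score - 1e-12 && best$a > 0L)) {
        cand <- bs[delta >= mx - 1e-12]
        lo <- pmin(reps[a], reps[cand]); hi <- pmax(reps[a], reps[cand])
        b <- cand[order(lo, hi)][1]
        if (mx > best$score + 1e-12 || best$a == 0L) {
          best <- list(score = mx, a = a, b = b)
        } else {
          # tie with the current best: smallest (min, max) word-id pair wins
          lo_new <- min(reps[a], reps[b]); hi_new <- max(reps[a], reps[b])
          lo_old <- min(reps[best$a], reps[best$b]); hi_old <- max(reps[best$a], reps[best$b])
          if (lo_new < lo_old || (lo_new == lo_old && hi_new < hi_old)) {
            best <- list(score = mx, a = a, b = b)
          }
        }
      }
    }
    best
  }

  add_word <- function(w) {
    # append word w as a new active cluster slot
    C_now <- nrow(N)
    row_w <- as.numeric(B[w, active_word_ids()])
    col_w <- as.numeric(B[active_word_ids(), w])
    # aggregate by cluster
    slot_of <- rep(seq_len(C_now), times = lengths(members))
    ordmem <- unlist(members)
    row_c <- as.numeric(rowsum(as.numeric(B[w, ordmem]), slot_of))
    col_c <- as.numeric(rowsum(as.numeric(B[ordmem, w]), slot_of))
    N2 <- rbind(cbind(N, col_c), c(row_c, as.numeric(B[w, w])))
    N <<- unname(N2)
    members[[C_now + 1L]] <<- w
    reps <<- c(reps, w)
  }
  active_word_ids <- function() unlist(members)

  remaining <- if (C < V) ord[(C + 1L):V] else integer(0)
  for (w in remaining) {
    add_word(w)
    bm <- best_merge()
    merge_pair(bm$a, bm$b)
  }
  while (nrow(N) > 1L) {
    bm <- best_merge()
    merge_pair(bm$a, bm$b)
  }
  merges <- if (length(merges)) do.call(rbind, merges) else
    data.frame(rep_kept = integer(), rep_gone = integer())
  structure(list(paths = paths, merges = merges, n_clusters = as.integer(n_clusters)),
            class = "brown_model")
}

#' Train a random indexing model
#'
#' Each vocabulary word receives a fixed sparse ternary index vector with
#' exactly `k` nonzero entries (half `+1`, half `-1`), generated from the
#' seed. A word's context vector is the sum, over all its corpus
#' occurrences, of the index vectors of neighboring words within the window
#' -- making the model exactly linear in the corpus.
#'
#' @param corpus Sentences (see [build_vocab()]).
#' @param vocab A [build_vocab()] result.
#' @param d Vector dimension.
#' @param k Number of nonzeros per index vector (even, `2 <= k <= d`).
#' @param window Symmetric context window size in tokens.
#' @param seed Integer seed for index-vector generation.
#' @return An `ri_model` list with `index` and `context` matrices (V x d).
#' @export
train_random_indexing <- function(corpus, vocab, d = 100L, k = 8L,
                                  window = 2L, seed = 1L) {
  V <- length(vocab$word)
  stopifnot(d >= k, k >= 2, k %% 2 == 0, window >= 1)
  index <- with_seed(seed, {
    m <- matrix(0, V, d)
    for (w in seq_len(V)) {
      dims <- sample.int(d, k)
      m[w, dims] <- rep(c(1, -1), each = k / 2)
    }
    m
  })
  ids <- corpus_ids(corpus, vocab)
  from <- integer(0); to <- integer(0)
  for (s in ids) {
    n <- length(s)
    if (n < 2) next
    for (o in seq_len(min(window, n - 1))) {
      i <- seq_len(n - o)
      from <- c(from, s[i], s[i + o])
      to <- c(to, s[i + o], s[i])
    }
  }
  context <- matrix(0, V, d)
  if (length(from)) {
    A <- Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(V, V))
    context <- as.matrix(A %*% index)
  }
  rownames(index) <- rownames(context) <- vocab$word
  structure(list(index = index, context = context, words = vocab$word,
                 d = as.integer(d), k = as.integer(k),
                 window = as.integer(window), seed = as.integer(seed)),
            class = "ri_model")
}

#' Loss and gradients for one skip-gram training pair
#'
#' Negative-sampling objective for a single (center, context) pair:
#' `-log sigmoid(u_o . v_c) - sum_n log sigmoid(-u_n . v_c)`.
#' Exposed separately so the analytic gradients can be checked against
#' finite differences.
#'
#' @param v_c Center word input vector.
#' @param u_o Context word output vector.
#' @param U_neg Matrix of negative-sample output vectors (rows).
#' @return List with `loss`, `grad_v`, `grad_u`, `grad_neg`.
#' @export
sg_pair_loss_grad <- function(v_c, u_o, U_neg) {
  s_pos <- stats::plogis(sum(u_o * v_c))
  s_neg <- stats::plogis(as.numeric(U_neg %*% v_c))
  loss <- -log(s_pos) - sum(log1p(-s_neg))
  g_pos <- s_pos - 1
  grad_v <- g_pos * u_o + as.numeric(crossprod(U_neg, s_neg))
  grad_u <- g_pos * v_c
  grad_neg <- outer(s_neg, v_c)
  list(loss = loss, grad_v = grad_v, grad_u = grad_u, grad_neg = grad_neg)
}

#' Train a skip-gram model with negative sampling
#'
#' Plain stochastic gradient descent over all (center, context) pairs within
#' the window, with `negatives` noise words per pair drawn from the unigram
#' distribution raised to the 3/4 power. Fixed seed gives bitwise-identical
#' embeddings.
#'
#' @param corpus Sentences (see [build_vocab()]).
#' @param vocab A [build_vocab()] result.
#' @param d Embedding dimension.
#' @param window Symmetric context window in tokens.
#' @param negatives Negative samples per pair.
#' @param epochs Training epochs.
#' @param lr Learning rate (constant).
#' @param seed Integer seed.
#' @return A `sg_model` list with `input` and `output` embedding matrices
#'   (V x d) and the training hyperparameters.
#' @export
train_skipgram <- function(corpus, vocab, d = 50L, window = 5L, negatives = 5L,
                           epochs = 5L, lr = 0.025, seed = 1L) {
  stopifnot(d >= 1, window >= 1, negatives >= 1, epochs >= 1, lr > 0)
  V <- length(vocab$word)
  ids <- corpus_ids(corpus, vocab)
  centers <- integer(0); contexts <- integer(0)
  for (s in ids) {
    n <- length(s)
    if (n < 2) next
    for (o in seq_len(min(window, n - 1))) {
      i <- seq_len(n - o)
      centers <- c(centers, s[i], s[i + o])
      contexts <- c(contexts, s[i + o], s[i])
    }
  }
  if (length(centers) == 0) stop("corpus has no context pairs")
  noise <- vocab$freq^0.75
  noise <- noise / sum(noise)
  with_seed(seed, {
    input <- matrix(stats::runif(V * d, -0.5, 0.5) / d, V, d)
    output <- matrix(0, V, d)
    np <- length(centers)
    for (ep in seq_len(epochs)) {
      perm <- sample.int(np)
      negs <- matrix(sample.int(V, np * negatives, replace = TRUE, prob = noise),
                     np, negatives)
      for (t in seq_len(np)) {
        p <- perm[t]
        c_id <- centers[p]; o_id <- contexts[p]
        ng <- negs[t, ]
        v <- input[c_id, ]
        g <- sg_pair_loss_grad(v, output[o_id, ], output[ng, , drop = FALSE])
        input[c_id, ] <- v - lr * g$grad_v
        output[o_id, ] <- output[o_id, ] - lr * g$grad_u
        output[ng, ] <- output[ng, ] - lr * g$grad_neg
      }
    }
    rownames(input) <- rownames(output) <- vocab$word
    structure(list(input = input, output = output, words = vocab$word,
                   d = as.integer(d), window = as.integer(window),
                   negatives = as.integer(negatives), epochs = as.integer(epochs),
                   lr = lr, seed = as.integer(seed)),
              class = "sg_model")
  })
}

# Mean negative-sampling loss of a model over (center, context) pairs of a
# corpus with fixed negatives; used to monitor training.
sg_corpus_loss <- function(model, corpus, vocab, negatives = 5L, seed = 1L) {
  ids <- corpus_ids(corpus, vocab)
  V <- length(vocab$word)
  noise <- vocab$freq^0.75; noise <- noise / sum(noise)
  with_seed(seed, {
    total <- 0; np <- 0L
    for (s in ids) {
      n <- length(s)
      if (n < 2) next
      for (i in seq_len(n - 1)) {
        ng <- sample.int(V, negatives, replace = TRUE, prob = noise)
        g <- sg_pair_loss_grad(model$input[s[i], ], model$output[s[i + 1], ],
                               model$output[ng, , drop = FALSE])
        total <- total + g$loss; np <- np + 1L
      }
    }
    total / max(np, 1L)
  })
}

#' Discretize a vector model into cluster-id features
#'
#' Runs k-means (fixed seed, fixed iteration cap) over the word vectors of a
#' random-indexing or skip-gram model and returns a word-to-cluster feature
#' map usable by [wr_features()].
#'
#' @param model An `ri_model` (context vectors) or `sg_model` (input
#'   embeddings).
#' @param n_clusters Number of clusters; must not exceed the vocabulary.
#' @param seed Integer seed for the k-means initialization.
#' @return A [wr_feature_map()] of type `"ri"` or `"skipgram"`.
#' @export
discretize <- function(model, n_clusters = 50L, seed = 1L) {
  vec <- if (inherits(model, "ri_model")) model$context
         else if (inherits(model, "sg_model")) model$input
         else stop("discretize expects an ri_model or sg_model")
  type <- if (inherits(model, "ri_model")) "ri" else "skipgram"
  V <- nrow(vec)
  if (n_clusters > V) stop("n_clusters (", n_clusters, ") exceeds vocabulary size (", V, ")")
  cl <- with_seed(seed, {
    uniq <- unique(vec)
    kk <- min(n_clusters, nrow(uniq))
    if (kk == nrow(uniq)) {
      # every distinct vector is its own cluster; kmeans rejects this case
      match(apply(vec, 1, paste, collapse = "\r"),
            apply(uniq, 1, paste, collapse = "\r"))
    } else {
      stats::kmeans(vec, centers = kk, iter.max = 50L, nstart = 3L)$cluster
    }
  })
  wr_feature_map(type, stats::setNames(as.character(cl), rownames(vec)))
}

#' Word-representation feature map
#'
#' A discrete word-to-feature lookup backing [wr_features()]: either Brown
#' bit paths or cluster ids.
#'
#' @param type `"brown"`, `"ri"` or `"skipgram"`.
#' @param map Named character vector, word to payload (bit path or cluster
#'   id).
#' @return A `wr_feature_map` object.
#' @export
wr_feature_map <- function(type, map) {
  stopifnot(type %in% c("brown", "ri", "skipgram"), !is.null(names(map)))
  structure(list(type = type, map = map), class = "wr_feature_map")
}

#' @rdname wr_feature_map
#' @param brown_model A `brown_model` from [train_brown()].
#' @export
brown_feature_map <- function(brown_model) {
  wr_feature_map("brown", brown_model$paths)
}

BROWN_PREFIX_LENGTHS <- c(4L, 6L, 10L, 20L)

# Feature names for one (lowercased) word under one map.
wr_lookup <- function(fmap, word) {
  payload <- fmap$map[word]
  if (is.na(payload)) return(paste0("wr:", fmap$type, ":UNK"))
  if (fmap$type == "brown") {
    len <- nchar(payload)
    ks <- BROWN_PREFIX_LENGTHS[BROWN_PREFIX_LENGTHS <= len]
    if (length(ks) == 0) ks <- len  # very short paths emit the full path
    unname(paste0("wr:brown:p", ks, "=", substr(rep(payload, length(ks)), 1, ks)))
  } else {
    unname(paste0("wr:", fmap$type, ":c=", payload))
  }
}

#' Save / load word-representation artifacts
#'
#' Text format: a one-line header `#chemner-wr <type> <dim> <seed>` followed
#' by `word<TAB>payload` lines, where the payload is a bit path, a cluster
#' id, or space-separated floats.
#'
#' @param x A `brown_model`, `ri_model`, `sg_model` or `wr_feature_map`.
#' @param path Output path.
#' @export
save_wr_model <- function(x, path) {
  if (inherits(x, "brown_model")) {
    header <- paste("#chemner-wr brown", x$n_clusters, 0)
    lines <- paste0(names(x$paths), "\t", x$paths)
  } else if (inherits(x, "ri_model")) {
    header <- paste("#chemner-wr ri", x$d, x$seed)
    lines <- paste0(x$words, "\t", apply(x$context, 1, paste, collapse = " "))
  } else if (inherits(x, "sg_model")) {
    header <- paste("#chemner-wr skipgram", x$d, x$seed)
    lines <- paste0(x$words, "\t", apply(x$input, 1, paste, collapse = " "))
  } else if (inherits(x, "wr_feature_map")) {
    header <- paste("#chemner-wr", paste0("map-", x$type), 0, 0)
    lines <- paste0(names(x$map), "\t", x$map)
  } else stop("unsupported word-representation object")
  writeLines(c(header, lines), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_wr_model
#' @return `load_wr_model()` returns a `wr_feature_map` for brown/map files
#'   or a list with a `vectors` matrix for ri/skipgram files.
#' @export
load_wr_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  if (hdr[1] != "#chemner-wr") stop("not a word-representation model file")
  type <- hdr[2]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  words <- vapply(body, `[`, character(1), 1)
  payload <- vapply(body, `[`, character(1), 2)
  if (type == "brown") {
    wr_feature_map("brown", stats::setNames(payload, words))
  } else if (startsWith(type, "map-")) {
    wr_feature_map(sub("^map-", "", type), stats::setNames(payload, words))
  } else {
    vec <- do.call(rbind, lapply(strsplit(payload, " ", fixed = TRUE), as.numeric))
    rownames(vec) <- words
    list(type = type, vectors = vec, d = as.integer(hdr[3]), seed = as.integer(hdr[4]))
  }
}
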