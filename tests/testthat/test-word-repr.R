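test_that("vocabulary construction pools rare words into <unk>", {
  v <- build_vocab(c("a a b"), min_count = 2)
  expect_setequal(v$word, c("a", "<unk>"))
  expect_equal(unname(v$freq[v$word == "a"]), 2L)
  v2 <- build_vocab(c("a a b"), min_count = 1)
  expect_setequal(v2$word, c("a", "b"))
  # frequency table sums to the corpus token count
  corp <- c("x y z x", "y y w")
  v3 <- build_vocab(corp, min_count = 1)
  expect_equal(sum(v3$freq), 7L)
  expect_error(build_vocab(character(0)), "empty")
})

test_that("two-word Brown clustering yields the unique one-merge tree", {
  corp <- c("a b", "a b", "b a")
  v <- build_vocab(corp)
  bm <- train_brown(corp, v, n_clusters = 2)
  expect_setequal(unname(bm$paths), c("0", "1"))
  expect_error(train_brown(corp, v, n_clusters = 3), "exceeds")
})

test_that("interchangeable word pairs merge first and paths are prefix-free", {
  # a,b share contexts exactly; c,d share contexts exactly
  corp <- rep(c("left a right", "left b right", "up c down", "up d down"), 10)
  v <- build_vocab(corp)
  bm <- train_brown(corp, v, n_clusters = length(v$word))
  p <- bm$paths
  # interchangeable pairs end up as siblings (differ only in the last bit)
  sib <- function(x, y) {
    nchar(p[x]) == nchar(p[y]) &&
      substr(p[x], 1, nchar(p[x]) - 1) == substr(p[y], 1, nchar(p[y]) - 1)
  }
  # only a~b and c~d are truly interchangeable (the frame words differ in
  # whether the content cluster follows or precedes them)
  expect_true(sib("a", "b"))
  expect_true(sib("c", "d"))
  # prefix-freeness: no path is a prefix of another
  for (i in seq_along(p)) for (j in seq_along(p)) {
    if (i != j) expect_false(startsWith(p[j], p[i]), info = paste(i, j))
  }
})

test_that("each greedy Brown merge is optimal against brute-force MI", {
  chemner:::with_seed(4, {
    for (trial in 1:3) {
      sents <- replicate(12, paste(sample(letters[1:6], sample(3:6, 1),
                                          replace = TRUE), collapse = " "))
      v <- build_vocab(sents)
      V <- length(v$word)
      ids <- chemner:::corpus_ids(sents, v)
      # first merge from singleton clusters, chosen by the implementation
      bm <- train_brown(sents, v, n_clusters = V)
      first <- bm$merges[1, ]
      # oracle: best achievable MI after any single pair merge
      best_mi <- -Inf
      for (i in seq_len(V - 1)) for (j in (i + 1):V) {
        assign <- seq_len(V); assign[j] <- i
        best_mi <- max(best_mi, brute_mi(ids, assign))
      }
      assign <- seq_len(V)
      assign[first$rep_gone] <- first$rep_kept
      expect_equal(as.numeric(brute_mi(ids, assign)), as.numeric(best_mi),
                   tolerance = 1e-10)
    }
  })
})

test_that("random indexing sums neighbor index vectors and is linear", {
  v <- build_vocab(c("a b"))
  m <- train_random_indexing(c("a b"), v, d = 10, k = 4, window = 1, seed = 3)
  expect_equal(m$context["a", ], m$index["b", ])
  expect_equal(m$context["b", ], m$index["a", ])
  expect_true(all(rowSums(m$index != 0) == 4))
  expect_true(all(rowSums(m$index) == 0))  # balanced +1/-1
  # word with no neighbors -> zero vector
  v2 <- build_vocab(c("x", "a b"))
  m2 <- train_random_indexing(c("x", "a b"), v2, d = 10, k = 4, window = 1, seed = 3)
  expect_true(all(m2$context["x", ] == 0))
  # determinism
  m3 <- train_random_indexing(c("a b"), v, d = 10, k = 4, window = 1, seed = 3)
  expect_identical(m, m3)
  # linearity: context of concatenated corpus = sum of the parts
  c1 <- c("a b a", "b b a")
  c2 <- c("a a b")
  va <- build_vocab(c(c1, c2))
  mA <- train_random_indexing(c1, va, d = 12, k = 4, window = 2, seed = 9)
  mB <- train_random_indexing(c2, va, d = 12, k = 4, window = 2, seed = 9)
  mAB <- train_random_indexing(c(c1, c2), va, d = 12, k = 4, window = 2, seed = 9)
  expect_equal(mAB$context, mA$context + mB$context)
})

test_that("skip-gram gradients match finite differences and training learns", {
  chemner:::with_seed(11, {
    for (trial in 1:5) {
      d <- 8
      v_c <- stats::rnorm(d); u_o <- stats::rnorm(d)
      U <- matrix(stats::rnorm(3 * d), 3, d)
      g <- sg_pair_loss_grad(v_c, u_o, U)
      eps <- 1e-6
      for (i in seq_len(d)) {
        e <- rep(0, d); e[i] <- eps
        fd <- (sg_pair_loss_grad(v_c + e, u_o, U)$loss -
                 sg_pair_loss_grad(v_c - e, u_o, U)$loss) / (2 * eps)
        expect_equal(g$grad_v[i], fd, tolerance = 1e-5)
        fd_u <- (sg_pair_loss_grad(v_c, u_o + e, U)$loss -
                   sg_pair_loss_grad(v_c, u_o - e, U)$loss) / (2 * eps)
        expect_equal(g$grad_u[i], fd_u, tolerance = 1e-5)
      }
    }
  })
  # two-word corpus: the aligned input/output pair grows together
  corp <- rep("a b", 30)
  v <- build_vocab(corp)
  m1 <- train_skipgram(corp, v, d = 10, window = 1, negatives = 2,
                       epochs = 1, seed = 5)
  m10 <- train_skipgram(corp, v, d = 10, window = 1, negatives = 2,
                        epochs = 15, seed = 5)
  score <- function(m) sum(m$input["a", ] * m$output["b", ])
  expect_gt(score(m10), score(m1))
  # loss decreases with training
  l1 <- chemner:::sg_corpus_loss(m1, corp, v, seed = 2)
  l10 <- chemner:::sg_corpus_loss(m10, corp, v, seed = 2)
  expect_lt(l10, l1)
  # determinism
  m1b <- train_skipgram(corp, v, d = 10, window = 1, negatives = 2,
                        epochs = 1, seed = 5)
  expect_identical(m1$input, m1b$input)
})

test_that("discretization recovers separable clusters deterministically", {
  v <- build_vocab(c(paste(letters[1:6], collapse = " ")))
  m <- train_random_indexing(c(paste(letters[1:6], collapse = " ")), v,
                             d = 4, k = 2, window = 1, seed = 1)
  # construct two well-separated groups by hand
  m$context <- rbind(matrix(stats::rnorm(12, 0, .05), 3),
                     matrix(stats::rnorm(12, 10, .05), 3))
  rownames(m$context) <- v$word
  fmap <- discretize(m, 2, seed = 1)
  cl <- fmap$map
  expect_length(unique(cl[1:3]), 1)
  expect_length(unique(cl[4:6]), 1)
  expect_false(cl[1] == cl[4])
  # n_clusters = V -> singleton clusters; > V errors
  fall <- discretize(m, 6, seed = 1)
  expect_length(unique(fall$map), 6)
  expect_error(discretize(m, 7, seed = 1), "exceeds")
  expect_identical(discretize(m, 2, seed = 1)$map, fmap$map)
})

test_that("word-representation models round-trip through their text format", {
  corp <- rep(c("a b c", "c b a"), 5)
  v <- build_vocab(corp)
  bm <- train_brown(corp, v, n_clusters = 3)
  tf <- withr::local_tempfile()
  save_wr_model(bm, tf)
  back <- load_wr_model(tf)
  expect_s3_class(back, "wr_feature_map")
  expect_identical(back$map[names(bm$paths)], bm$paths)
  ri <- train_random_indexing(corp, v, d = 6, k = 2, window = 1, seed = 2)
  save_wr_model(ri, tf)
  back2 <- load_wr_model(tf)
  expect_equal(back2$vectors[v$word, ], ri$context[v$word, ], tolerance = 1e-12)
  fmap <- discretize(ri, 2, seed = 1)
  save_wr_model(fmap, tf)
  back3 <- load_wr_model(tf)
  expect_identical(back3$map, fmap$map)
  expect_identical(back3$type, "ri")
})
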