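test_that("sequence scores are additive and respect the weights", {
  m <- sequence_model(feature_index = stats::setNames(1:2, c("f1", "f2")))
  expect_equal(score_sequence(m, list("f1"), "B"), 0)
  m$W[1, 1] <- 2.5
  expect_equal(score_sequence(m, list("f1"), "B"), 2.5)
  expect_error(score_sequence(m, list("f1"), "Q"), "unknown label")
  # additivity: concatenation = sum of halves + one linking transition
  chemner:::with_seed(5, {
    m2 <- random_toy_model()
    fa <- random_toy_features(3, names(m2$feature_index))
    fb <- random_toy_features(2, names(m2$feature_index))
    la <- sample(m2$labels, 3, replace = TRUE)
    lb <- sample(m2$labels, 2, replace = TRUE)
    lhs <- score_sequence(m2, c(fa, fb), c(la, lb))
    rhs <- score_sequence(m2, fa, la) + score_sequence(m2, fb, lb) +
      m2$Trans[match(la[3], m2$labels), match(lb[1], m2$labels)]
    expect_equal(lhs, rhs)
  })
})

test_that("Viterbi and forward-backward agree with exhaustive enumeration", {
  chemner:::with_seed(21, {
    for (trial in 1:25) {
      m <- random_toy_model()
      n <- sample(1:8, 1)
      feats <- random_toy_features(n, names(m$feature_index))
      oracle <- enumerate_scores(m, feats)
      v <- viterbi(m, feats, mask_illegal = FALSE)
      expect_equal(score_sequence(m, feats, v), max(oracle$scores),
                   tolerance = 1e-10)
      fb <- forward_backward(m, feats)
      expect_equal(fb$logZ, chemner:::logsumexp(oracle$scores),
                   tolerance = 1e-10)
      expect_equal(unname(rowSums(fb$posteriors)), rep(1, n), tolerance = 1e-12)
      # posterior of a position against weighted enumeration
      w <- exp(oracle$scores - fb$logZ)
      t0 <- sample(n, 1)
      post_oracle <- vapply(seq_along(m$labels),
                            function(l) sum(w[oracle$grid[, t0] == l]), numeric(1))
      expect_equal(unname(fb$posteriors[t0, ]), post_oracle, tolerance = 1e-10)
    }
  })
})

test_that("zero weights give closed-form inference results", {
  m <- sequence_model(feature_index = stats::setNames(1:3, c("a", "b", "c")))
  feats <- list("a", c("b", "c"), "a")
  expect_equal(forward_backward(m, feats)$logZ, 3 * log(3))
  expect_true(all(abs(forward_backward(m, feats)$posteriors - 1 / 3) < 1e-12))
  # zero transitions -> per-position argmax of summed emissions
  # (position 2 carries features b and c: emissions (0, 2, 3), argmax O)
  m$W <- matrix(c(1, 0, 0, 0, 2, 0, 0, 0, 3), 3, 3, byrow = TRUE)
  expect_equal(viterbi(m, feats, mask_illegal = FALSE), c("B", "O", "B"))
})

test_that("decode-time masking forbids orphan I labels", {
  chemner:::with_seed(31, {
    for (trial in 1:10) {
      m <- random_toy_model()
      feats <- random_toy_features(6, names(m$feature_index))
      v <- viterbi(m, feats, mask_illegal = TRUE)
      prev <- c("O", v[-length(v)])
      expect_false(any(v == "I" & prev == "O"))
    }
  })
})

test_that("CRF loss and gradient match closed form and finite differences", {
  labels <- c("B", "I", "O")
  # zero weights, single sequence -> loss = n log L
  m0 <- sequence_model(labels, stats::setNames(1:4, paste0("f", 1:4)))
  data0 <- list(list(features = list("f1", "f2", c("f3", "f4")),
                     labels = c("B", "I", "O")))
  expect_equal(crf_loss_grad(m0, data0, l2 = 0)$loss, 3 * log(3))
  # finite differences at random points
  chemner:::with_seed(41, {
    for (trial in 1:5) {
      m <- random_toy_model(n_feats = 6)
      data <- lapply(1:3, function(s) {
        n <- sample(2:5, 1)
        list(features = random_toy_features(n, names(m$feature_index)),
             labels = sample(labels, n, replace = TRUE))
      })
      g <- crf_loss_grad(m, data, l2 = 0.3)
      eps <- 1e-6
      for (k in 1:6) {
        i <- sample(6, 1); j <- sample(3, 1)
        mp <- m; mp$W[i, j] <- mp$W[i, j] + eps
        mm <- m; mm$W[i, j] <- mm$W[i, j] - eps
        fd <- (crf_loss_grad(mp, data, 0.3)$loss -
                 crf_loss_grad(mm, data, 0.3)$loss) / (2 * eps)
        expect_equal(g$grad$W[i, j], fd, tolerance = 1e-5)
      }
      i <- sample(3, 1); j <- sample(3, 1)
      mp <- m; mp$Trans[i, j] <- mp$Trans[i, j] + eps
      mm <- m; mm$Trans[i, j] <- mm$Trans[i, j] - eps
      fd <- (crf_loss_grad(mp, data, 0.3)$loss -
               crf_loss_grad(mm, data, 0.3)$loss) / (2 * eps)
      expect_equal(g$grad$Trans[i, j], fd, tolerance = 1e-5)
    }
  })
})

test_that("CRF negative log-likelihood is convex along random rays", {
  chemner:::with_seed(51, {
    m <- random_toy_model(n_feats = 5)
    data <- lapply(1:3, function(s) {
      n <- sample(3:5, 1)
      list(features = random_toy_features(n, names(m$feature_index)),
           labels = sample(m$labels, n, replace = TRUE))
    })
    for (ray in 1:5) {
      dW <- matrix(stats::rnorm(15), 5); dT <- matrix(stats::rnorm(9), 3)
      at <- function(t) {
        mt <- m; mt$W <- m$W + t * dW; mt$Trans <- m$Trans + t * dT
        crf_loss_grad(mt, data, l2 = 0)$loss
      }
      # midpoint convexity on a random segment
      f0 <- at(-0.5); f1 <- at(0.5); fm <- at(0)
      expect_lte(fm, (f0 + f1) / 2 + 1e-9)
    }
  })
})

test_that("CRF training separates separable data and shrinks with more L2", {
  data <- separable_toy_data()
  m <- train_crf(data, training_config("CRF", l2 = 0.1))
  for (s in data) {
    expect_equal(viterbi(m, s$features), s$labels)
  }
  # determinism
  m2 <- train_crf(data, training_config("CRF", l2 = 0.1))
  expect_identical(m$W, m2$W)
  # monotone weight-norm shrinkage over an l2 grid
  norms <- vapply(c(0.1, 1, 10), function(l2) {
    mt <- train_crf(data, training_config("CRF", l2 = l2))
    sum(mt$W^2) + sum(mt$Trans^2)
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("loss-augmented decoding maximizes score plus Hamming distance", {
  chemner:::with_seed(61, {
    for (trial in 1:10) {
      m <- random_toy_model()
      n <- sample(2:6, 1)
      feats <- random_toy_features(n, names(m$feature_index))
      gold <- sample(m$labels, n, replace = TRUE)
      yhat <- loss_augmented_viterbi(m, feats, gold)
      oracle <- enumerate_scores(m, feats)
      aug <- oracle$scores +
        apply(oracle$grid, 1, function(y) sum(m$labels[y] != gold))
      got <- score_sequence(m, feats, yhat) + sum(yhat != gold)
      expect_equal(got, max(aug), tolerance = 1e-10)
    }
    # zero weights: the most violating labeling is maximally different
    m0 <- sequence_model(feature_index = stats::setNames(1:2, c("a", "b")))
    gold <- c("B", "O", "I")
    yhat <- loss_augmented_viterbi(m0, list("a", "b", "a"), gold)
    expect_equal(sum(yhat != gold), 3)
    # cost 0 reduces to unmasked Viterbi
    m <- random_toy_model()
    feats <- random_toy_features(4, names(m$feature_index))
    expect_equal(loss_augmented_viterbi(m, feats, c("B", "B", "B", "B"), cost = 0),
                 viterbi(m, feats, mask_illegal = FALSE))
  })
})

test_that("SSVM training reaches zero hinge loss on separable data", {
  data <- separable_toy_data()
  cfg <- training_config("SSVM", C = 1, epochs = 12, seed = 3)
  m <- train_ssvm(data, cfg)
  for (s in data) expect_equal(viterbi(m, s$features), s$labels)
  # objective trend decreases
  trace <- m$config$objective_trace
  expect_lt(trace[length(trace)], trace[1])
  # determinism under the same seed
  m2 <- train_ssvm(data, cfg)
  expect_identical(m$W, m2$W)
})

test_that("models round-trip through serialization", {
  data <- separable_toy_data(n_seq = 6)
  m <- train_crf(data, training_config("CRF", l2 = 1))
  tf <- withr::local_tempfile(fileext = ".rds")
  save_model(m, tf)
  back <- load_model(tf)
  expect_identical(back$W, m$W)
  expect_identical(back$Trans, m$Trans)
  expect_identical(back$feature_index, m$feature_index)
  expect_identical(back$labels, m$labels)
})
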