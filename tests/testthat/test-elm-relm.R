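test_that("hidden layers are seeded, shaped and Uniform(-1, 1)", {
  a <- random_hidden_layer(3, 5, seed = 2)
  b <- random_hidden_layer(3, 5, seed = 2)
  expect_identical(a, b)
  expect_equal(dim(a$input_weights), c(5L, 3L))
  expect_length(a$biases, 5)
  one <- random_hidden_layer(1, 1, seed = 1)
  expect_equal(dim(one$input_weights), c(1L, 1L))

  big <- random_hidden_layer(100, 1000, seed = 3)
  draws <- c(big$input_weights, big$biases)
  expect_lt(abs(mean(draws)), 0.02)
  expect_true(all(draws > -1 & draws < 1))
  expect_gt(max(draws), 0.99)          # fills the stated range
  expect_lt(min(draws), -0.99)
})

test_that("hidden activations follow g(w.x + b)", {
  W0 <- matrix(0, 4, 2)
  H <- hidden_output(W0, rep(0, 4), "sigmoid", matrix(rnorm(6), 3, 2))
  expect_true(all(H == 0.5))
  H2 <- hidden_output(matrix(2, 1, 1), -1, "sigmoid", matrix(1, 1, 1))
  expect_equal(H2[1, 1], 1 / (1 + exp(-1)), tolerance = 1e-15)
  H3 <- hidden_output(W0, rep(0, 4), "tanh", matrix(rnorm(6), 3, 2))
  expect_true(all(H3 == 0))
  expect_error(hidden_output(W0, rep(0, 4), "gauss", matrix(0, 1, 2)),
               "unknown activation")
})

test_that("ELM weights solve the least-squares problem (oracle check)", {
  expect_equal(fit_elm(matrix(rnorm(12), 4, 3), matrix(0, 4, 2)),
               matrix(0, 3, 2), tolerance = 1e-12)
  set.seed(14)
  Hsq <- matrix(rnorm(25), 5, 5)
  Tsq <- admorph:::one_hot(sample(c("a", "b"), 5, TRUE), c("a", "b"))
  expect_equal(Hsq %*% fit_elm(Hsq, Tsq), Tsq, tolerance = 1e-8)

  H <- matrix(rnorm(300), 30, 10)
  Tm <- admorph:::one_hot(sample(c("a", "b", "c"), 30, TRUE),
                          c("a", "b", "c"))
  expect_equal(fit_elm(H, Tm), oracle_lstsq(H, Tm), tolerance = 1e-8)
})

test_that("RELM solves the ridge system and bridges to plain ELM", {
  set.seed(15)
  H <- matrix(rnorm(40 * 15), 40, 15)
  Tm <- admorph:::one_hot(sample(c("a", "b", "c"), 40, TRUE),
                          c("a", "b", "c"))
  expect_equal(fit_relm(H, Tm, C = 1), oracle_ridge(H, Tm, 1),
               tolerance = 1e-8)
  expect_equal(fit_relm(H, Tm, C = 1e12), fit_elm(H, Tm), tolerance = 1e-6)
  b_small <- fit_relm(H, Tm, C = 1e-12)
  expect_lte(sqrt(sum(b_small^2)), 1e-9 * sqrt(sum(crossprod(H, Tm)^2)))
  expect_error(fit_relm(H, Tm, C = 0), "positive")
  expect_error(fit_relm(H, Tm, C = -3), "positive")
})

test_that("RELM norm grows and residual shrinks as C increases", {
  set.seed(16)
  H <- matrix(rnorm(35 * 12), 35, 12)
  Tm <- admorph:::one_hot(sample(c("a", "b"), 35, TRUE), c("a", "b"))
  Cs <- 10^seq(-3, 3)
  norms <- resid <- numeric(length(Cs))
  for (i in seq_along(Cs)) {
    bta <- fit_relm(H, Tm, Cs[i])
    norms[i] <- sqrt(sum(bta^2))
    resid[i] <- sqrt(sum((H %*% bta - Tm)^2))
  }
  expect_true(all(diff(norms) >= -1e-10))
  expect_true(all(diff(resid) <= 1e-10))
})

test_that("score prediction is h(X) beta with the first-class tie rule", {
  set.seed(17)
  b <- make_blobs(n_per = 10, K = 3, seed = 9)
  m <- train_elm(b$X, b$y, L = 40, C = 10, seed = 5, classes = b$classes)
  S <- predict_scores(m, b$X)
  Hm <- hidden_output(m$input_weights, m$biases, "sigmoid", b$X)
  expect_equal(S, Hm %*% m$beta, tolerance = 1e-12, ignore_attr = TRUE)
  m0 <- m; m0$beta <- 0 * m0$beta
  expect_true(all(predict(m0, b$X) == b$classes[1]))

  # exact interpolation (square well-conditioned system) reproduces labels
  Xs <- matrix(rnorm(24), 12, 2)
  ys <- rep(c("a", "b"), 6)
  ms <- train_elm(Xs, ys, L = 12, C = Inf, seed = 7, classes = c("a", "b"))
  expect_identical(predict(ms, Xs), ys)
})

test_that("reliability is the top-two score margin", {
  expect_equal(reliability(c(0.9, 0.1)), 0.8)
  expect_equal(reliability(c(0.4, 0.4, 0.2)), 0)
  expect_error(reliability(0.7), "at least 2")
  set.seed(18)
  for (i in 1:20) {
    r <- rnorm(4)
    s <- sort(r, decreasing = TRUE)
    expect_equal(reliability(r), s[1] - s[2])
    expect_gte(reliability(r), 0)
  }
})

test_that("sparse-representation fallback picks the reconstructing class", {
  set.seed(19)
  D <- matrix(rnorm(20 * 30), 20, 30)
  labs <- rep(c("NC", "MCI", "AD", "NC", "MCI"), each = 4)
  # exact atom membership
  expect_identical(
    sparse_fallback_classify(D, labs, D[7, ], classes = c("NC", "MCI", "AD")),
    labs[7])
  # dominant atom under small perturbation, orthogonal 2-atom dictionary
  D2 <- rbind(c(1, 0, 0), c(0, 1, 0))
  x <- c(1, 0, 0) + c(0, 0.01, 0.01)
  expect_identical(sparse_fallback_classify(D2, c("a", "b"), x,
                                            classes = c("a", "b")), "a")
})

test_that("OMP labels agree with exhaustive 2-atom support search", {
  classes <- c("NC", "MCI", "AD")
  for (s in 1:10) {
    set.seed(200 + s)
    D <- matrix(rnorm(20 * 30), 20, 30)
    labs <- sample(rep(classes, length.out = 20))
    A <- t(D) / rep(sqrt(rowSums(D^2)), each = 30)
    mix <- sample(20, 2)
    x <- 0.9 * A[, mix[1]] + 0.35 * A[, mix[2]]
    x <- x / sqrt(sum(x^2))
    # oracle: best residual over all 2-atom supports, then class residuals
    best <- NULL; best_res <- Inf
    for (i in 1:19) for (j in (i + 1):20) {
      co <- qr.coef(qr(A[, c(i, j)]), x)
      res <- sqrt(sum((x - A[, c(i, j)] %*% co)^2))
      if (res < best_res) { best_res <- res; best <- list(c(i, j), co) }
    }
    cls_res <- vapply(classes, function(cl) {
      sel <- labs[best[[1]]] == cl
      approx_c <- if (any(sel)) A[, best[[1]][sel], drop = FALSE] %*%
        best[[2]][sel] else 0 * x
      sqrt(sum((x - approx_c)^2))
    }, numeric(1))
    oracle_label <- classes[which.min(cls_res)]
    expect_identical(
      sparse_fallback_classify(D, labs, x, n_nonzero = 2, classes = classes),
      oracle_label)
  }
})

test_that("the reliability gate routes exactly as the margins dictate", {
  set.seed(20)
  b <- make_blobs(n_per = 15, K = 3, sep = 2, seed = 10)
  m <- train_elm(b$X, b$y, L = 60, C = 1, seed = 3, classes = b$classes,
                 keep_dictionary = TRUE)
  Xt <- make_blobs(n_per = 10, K = 3, sep = 2, seed = 11)$X
  # threshold 0: identical to pure argmax prediction
  expect_identical(predict_hybrid(m, Xt, threshold = 0), predict(m, Xt))
  # threshold Inf: every row routed to the sparse fallback
  all_fallback <- vapply(seq_len(nrow(Xt)), function(i)
    sparse_fallback_classify(m$dictionary$X, m$dictionary$labels, Xt[i, ],
                             classes = m$classes), character(1))
  expect_identical(predict_hybrid(m, Xt, threshold = Inf), all_fallback)
  # intermediate threshold: routing mask recomputed from reliability
  thr <- stats::median(apply(predict_scores(m, Xt), 1, reliability))
  S <- predict_scores(m, Xt)
  expected <- vapply(seq_len(nrow(Xt)), function(i) {
    if (reliability(S[i, ]) >= thr) m$classes[which.max(S[i, ])]
    else all_fallback[i]
  }, character(1))
  expect_identical(predict_hybrid(m, Xt, threshold = thr), expected)
  # gate without a dictionary is a configuration error
  m_nd <- train_elm(b$X, b$y, L = 20, seed = 3, classes = b$classes)
  expect_error(predict_hybrid(m_nd, Xt, threshold = 0.1), "dictionary")
})
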