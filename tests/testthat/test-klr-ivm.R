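test_that("kernel matrix matches hand evaluation and limit cases", {
  A <- rbind(c(0, 0), c(3, 4))
  k <- kernel_matrix(A, A, kernel_spec("rbf", gamma = 0.02))
  expect_equal(diag(k), c(1, 1))                      # k(x, x) = exp(0)
  expect_equal(k[1, 2], exp(-0.5), tolerance = 1e-12) # gamma * 25 = 0.5
  expect_true(isSymmetric(k))
  k0 <- kernel_matrix(A, A, kernel_spec("rbf", gamma = 1e-12))
  expect_true(all(abs(k0 - 1) < 1e-10))
  expect_equal(kernel_matrix(A, A, kernel_spec("linear")), A %*% t(A))
  expect_error(kernel_matrix(A, matrix(0, 1, 3), kernel_spec("linear")),
               "dimension mismatch")
})

test_that("dominating penalty shrinks KLR to the class priors", {
  set.seed(8)
  X <- matrix(rnorm(30 * 2), 30, 2)
  y <- rep(c("a", "b"), times = c(10, 20))
  m <- fit_klr(X, y, kernel_spec("rbf", 0.5), lambda = 1e6,
               classes = c("a", "b"))
  P <- predict_proba(m, X)
  expect_equal(unname(colMeans(P)), c(1 / 3, 2 / 3), tolerance = 0.01)
})

test_that("separable 1-D toy data is fit perfectly", {
  X <- matrix(c(-2, -1, 1, 2), 4, 1)
  y <- c("neg", "neg", "pos", "pos")
  m <- fit_klr(X, y, kernel_spec("rbf", 0.5), lambda = 0.01,
               classes = c("neg", "pos"))
  expect_identical(predict(m, X), y)
})

test_that("the Newton optimum matches a quasi-Newton oracle on 3 classes", {
  set.seed(9)
  X <- matrix(rnorm(12 * 2), 12, 2)
  y_int <- rep(1:3, each = 4)
  classes <- c("NC", "MCI", "AD")
  gamma <- 0.7; lambda <- 0.1
  m <- fit_klr(X, classes[y_int], kernel_spec("rbf", gamma),
               lambda = lambda, classes = classes)
  q_pkg <- admorph:::klr_objective(
    m$weights, cbind(kernel_matrix(X, X, m$kernel), 1),
    admorph:::one_hot(classes[y_int], classes),
    kernel_matrix(X, X, m$kernel), lambda)
  q_oracle <- oracle_klr_optim(X, y_int, 3, gamma, lambda)
  expect_lt(abs(q_pkg - q_oracle), 1e-5)
})

test_that("analytic gradient matches central differences", {
  set.seed(10)
  X <- matrix(rnorm(8 * 2), 8, 2)
  y <- c("a", "b", "c", "a", "b", "c", "a", "b")
  classes <- c("a", "b", "c")
  kern <- kernel_spec("rbf", 0.6)
  Knn <- kernel_matrix(X, X, kern)
  Z <- cbind(Knn, 1)
  Y <- admorph:::one_hot(y, classes)
  theta <- matrix(rnorm(9 * 2, sd = 0.3), 9, 2)
  G <- admorph:::klr_gradient(theta, Z, Y, Knn, 0.2)
  h <- 1e-5
  for (idx in sample(length(theta), 6)) {
    tp <- theta; tm <- theta
    tp[idx] <- tp[idx] + h; tm[idx] <- tm[idx] - h
    num <- (admorph:::klr_objective(tp, Z, Y, Knn, 0.2) -
              admorph:::klr_objective(tm, Z, Y, Knn, 0.2)) / (2 * h)
    expect_equal(G[idx], num, tolerance = 1e-5)
  }
})

test_that("posterior rows are stochastic and match the sigmoid at K = 2", {
  set.seed(11)
  b <- make_blobs(n_per = 15, K = 3, seed = 2)
  m <- fit_klr(b$X, b$y, kernel_spec("rbf", 0.3), lambda = 0.05,
               classes = b$classes)
  P <- predict_proba(m, b$X)
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-12)
  expect_true(all(P > 0 & P < 1))
  expect_identical(predict(m, b$X), b$classes[apply(P, 1, which.max)])

  b2 <- make_blobs(n_per = 10, K = 2, seed = 3)
  m2 <- fit_klr(b2$X, b2$y, kernel_spec("rbf", 0.3), lambda = 0.05,
                classes = b2$classes)
  Kx <- kernel_matrix(b2$X, m2$reference_points, m2$kernel)
  f <- as.numeric(cbind(Kx, 1) %*% m2$weights)
  expect_equal(predict_proba(m2, b2$X)[, 1], 1 / (1 + exp(-f)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a hand-built model reproduces hand-computed softmax and ties", {
  ref <- matrix(c(0, 1), 2, 1)
  m <- admorph:::new_klr_model(kernel_spec("linear"), ref,
                               matrix(c(1, -1, 0.5, 0, 0, 0), 3, 2),
                               0, c("x", "y", "z"), "gram")
  x <- matrix(2, 1, 1)
  f <- c(sum(c(0, 2) * c(1, -1)) + 0.5, 0, 0)  # k(x, ref) = (0, 2)
  expect_equal(as.numeric(predict_proba(m, x)), exp(f) / sum(exp(f)),
               tolerance = 1e-12)
  # exact tie between the last two classes resolves to the earlier one
  m_tie <- admorph:::new_klr_model(kernel_spec("linear"), ref,
                                   matrix(0, 3, 2), 0, c("x", "y", "z"),
                                   "gram")
  expect_identical(predict(m_tie, x), "x")
})

test_that("single-class input and bad lambda are rejected", {
  X <- matrix(rnorm(6), 3, 2)
  expect_error(fit_klr(X, c("a", "a", "a")), "2 classes")
  expect_error(fit_klr(X, c("a", "b", "a"), lambda = -1), "lambda")
})

test_that("epsilon = 0 greedy selection recovers the full KLR model", {
  set.seed(12)
  b <- make_blobs(n_per = 8, K = 2, seed = 4)
  kern <- kernel_spec("rbf", 0.2)
  full <- fit_klr(b$X, b$y, kern, lambda = 0.1, classes = b$classes)
  iv <- fit_ivm(b$X, b$y, kern, lambda = 0.1, epsilon = 0,
                max_import = nrow(b$X), classes = b$classes)
  expect_setequal(iv$report$import_indices, seq_len(nrow(b$X)))
  expect_true(iv$report$stopped_reason %in% c("exhausted", "max_size"))
  Knn <- kernel_matrix(b$X, b$X, kern)
  Y <- admorph:::one_hot(b$y, b$classes)
  q_full <- admorph:::klr_objective(full$weights, cbind(Knn, 1), Y, Knn, 0.1)
  ord <- iv$report$import_indices
  q_ivm <- admorph:::klr_objective(
    iv$model$weights, cbind(Knn[, ord], 1), Y, Knn[ord, ord], 0.1)
  expect_lt(abs(q_full - q_ivm), 1e-4)
})

test_that("two greedy steps equal brute-force enumeration on 6 points", {
  classes <- c("p", "q")
  for (s in 1:20) {
    set.seed(100 + s)
    X <- matrix(rnorm(12), 6, 2)
    y <- sample(rep(classes, 3))
    kern <- kernel_spec("rbf", 0.8)
    Knn <- kernel_matrix(X, X, kern)
    y_int <- match(y, classes)
    # oracle: exhaustive ordered greedy with independent refits
    subset_q <- function(cols) {
      p <- (length(cols) + 1L)
      fit <- stats::optim(rep(0, p), oracle_klr_objective, X = X,
                          y_int = y_int, K = 2,
                          ref = X[cols, , drop = FALSE], gamma = 0.8,
                          lambda = 0.1, method = "BFGS",
                          control = list(maxit = 5000, reltol = 1e-14))
      fit$value
    }
    q1 <- vapply(1:6, function(j) subset_q(j), numeric(1))
    first <- which.min(q1)
    rest <- setdiff(1:6, first)
    q2 <- vapply(rest, function(j) subset_q(c(first, j)), numeric(1))
    oracle_pair <- c(first, rest[which.min(q2)])

    iv <- fit_ivm(X, y, kern, lambda = 0.1, epsilon = 0, max_import = 2,
                  exact_refit = TRUE, classes = classes)
    expect_identical(iv$report$import_indices, oracle_pair)
  }
})

test_that("sparse import sets track full KLR on separated blobs", {
  b <- make_blobs(n_per = 30, K = 2, sep = 5, seed = 6)
  kern <- kernel_spec("rbf", 0.3)
  test <- make_blobs(n_per = 40, K = 2, sep = 5, seed = 7)
  iv <- fit_ivm(b$X, b$y, kern, lambda = 0.1, epsilon = 0.01, delta_t = 1,
                classes = b$classes)
  expect_lte(length(iv$report$import_indices), 10)
  expect_identical(iv$report$stopped_reason, "converged")
  full <- fit_klr(b$X, b$y, kern, lambda = 0.1, classes = b$classes)
  acc_iv <- mean(predict(iv$model, test$X) == test$y)
  acc_full <- mean(predict(full, test$X) == test$y)
  expect_gte(acc_iv, acc_full - 0.02)
})

test_that("the IVM objective trace is monotone non-increasing", {
  b <- make_blobs(n_per = 12, K = 3, seed = 8)
  iv <- fit_ivm(b$X, b$y, kernel_spec("rbf", 0.4), lambda = 0.1,
                epsilon = 0, max_import = 12, classes = b$classes)
  expect_true(all(diff(iv$report$objective_trace) <= 1e-10))
  expect_false(anyDuplicated(iv$report$import_indices) > 0)
})
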