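#' Draw a random hidden layer
#'
#' ELM hidden-layer parameters are never trained: input weights and biases
#' are drawn i.i.d. Uniform(-1, 1) before any data are seen, and are a pure
#' function of \code{(d, L, seed)}.
#'
#' @param d input dimension. @param L number of hidden nodes. @param seed
#'   integer seed.
#' @return list with \code{input_weights} (L x d) and \code{biases}
#'   (length L).
#' @export
random_hidden_layer <- function(d, L, seed) {
  if (d < 1 || L < 1) stop("d and L must be >= 1")
  with_seed(seed, {
    list(input_weights = matrix(stats::runif(L * d, -1, 1), L, d),
         biases = stats::runif(L, -1, 1))
  })
}

#' Hidden-layer output matrix
#'
#' \code{H[j, i] = g(w_i . x_j + b_i)} for activation g.
#'
#' @param input_weights L x d matrix. @param biases length-L vector.
#' @param activation \code{"sigmoid"}, \code{"tanh"} or \code{"relu"}.
#' @param X N x d data matrix.
#' @return N x L matrix of activations.
#' @export
hidden_output <- function(input_weights, biases, activation, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(input_weights))
    stop("X has ", ncol(X), " columns; hidden layer expects ",
         ncol(input_weights))
  A <- X %*% t(input_weights)
  A <- sweep(A, 2, biases, "+")
  switch(activation,
         sigmoid = 1 / (1 + exp(-A)),
         tanh = tanh(A),
         relu = pmax(A, 0),
         stop("unknown activation '", activation, "'"))
}

# Moore-Penrose pseudoinverse via SVD (tolerance as in pinv conventions).
pseudo_inverse <- function(H) {
  sv <- svd(H)
  tol <- max(dim(H)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) return(matrix(0, ncol(H), nrow(H)))
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' Closed-form ELM output weights
#'
#' \code{beta = pinv(H) \%*\% T}: the minimum-norm least-squares solution
#' mapping hidden activations to one-hot targets.
#'
#' @param H N x L hidden output matrix. @param targets N x K matrix
#'   (one-hot rows for classification).
#' @return L x K output-weight matrix.
#' @export
fit_elm <- function(H, targets) {
  H <- as.matrix(H); targets <- as.matrix(targets)
  if (nrow(H) != nrow(targets))
    stop("H and targets disagree in row count")
  pseudo_inverse(H) %*% targets
}

#' Ridge-regularized ELM output weights
#'
#' Solves \code{beta = (I/C + H'H)^{-1} H'T} exactly, via a symmetric
#' positive-definite (Cholesky) solve rather than explicit inversion. As C
#' grows the solution approaches the plain ELM least-squares weights; as C
#' shrinks the weights shrink to zero.
#'
#' @inheritParams fit_elm
#' @param C positive regularization constant (larger C = weaker ridge).
#' @return L x K output-weight matrix.
#' @export
fit_relm <- function(H, targets, C = 1) {
  if (!is.numeric(C) || length(C) != 1 || C <= 0)
    stop("C must be a positive scalar")
  H <- as.matrix(H); targets <- as.matrix(targets)
  if (nrow(H) != nrow(targets))
    stop("H and targets disagree in row count")
  A <- crossprod(H)
  diag(A) <- diag(A) + 1 / C
  ch <- tryCatch(chol(A), error = function(e) NULL)
  rhs <- crossprod(H, targets)
  if (is.null(ch)) return(solve(A, rhs))
  backsolve(ch, forwardsolve(t(ch), rhs))
}

#' Train an (R)ELM classifier
#'
#' Random hidden layer + closed-form output weights. \code{C = Inf}
#' encodes the plain (unregularized, pseudoinverse) ELM. Targets are the
#' one-hot encoding in \{0, 1\} of the class labels.
#'
#' @param X N x d training matrix. @param labels class labels.
#' @param L hidden nodes; default \code{min(1000, 10 * N)}.
#' @param C ridge constant (\code{Inf} = plain ELM).
#' @param activation activation name.
#' @param seed integer seed for the hidden layer.
#' @param classes ordered class set; default order of appearance.
#' @param keep_dictionary retain the training matrix + labels so the
#'   sparse-representation fallback of \code{\link{predict_hybrid}} is
#'   available.
#' @return an object of class \code{elm_model}.
#' @export
train_elm <- function(X, labels, L = NULL, C = Inf,
                      activation = "sigmoid", seed = 1, classes = NULL,
                      keep_dictionary = FALSE) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (is.null(classes)) classes <- unique(labels)
  N <- nrow(X)
  if (is.null(L)) L <- min(1000L, 10L * N)
  hl <- random_hidden_layer(ncol(X), L, seed)
  H <- hidden_output(hl$input_weights, hl$biases, activation, X)
  Tm <- one_hot(labels, classes)
  beta <- if (is.infinite(C)) fit_elm(H, Tm) else fit_relm(H, Tm, C)
  structure(list(input_weights = hl$input_weights, biases = hl$biases,
                 activation = activation, beta = beta, C = C,
                 classes = classes, seed = as.integer(seed),
                 dictionary = if (keep_dictionary)
                   list(X = X, labels = labels) else NULL),
            class = "elm_model")
}

#' Class scores of an (R)ELM model
#'
#' @param model an \code{elm_model}. @param X m x d matrix.
#' @return m x K score matrix \code{h(X) \%*\% beta}; the predicted label
#'   is the argmax with ties toward the earlier class.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "elm_model"))
  H <- hidden_output(model$input_weights, model$biases, model$activation,
                     X)
  S <- H %*% model$beta
  colnames(S) <- model$classes
  S
}

#' @export
predict.elm_model <- function(object, X, ...) {
  S <- predict_scores(object, X)
  object$classes[apply(S, 1, which.max)]
}

#' Score-margin reliability of a prediction
#'
#' The gap between the largest and second-largest class scores; small
#' margins flag test samples whose ELM decision is unreliable and should
#' be routed to the sparse-representation fallback.
#'
#' @param scores_row numeric vector of K >= 2 class scores.
#' @return non-negative margin top1 - top2.
#' @export
reliability <- function(scores_row) {
  if (length(scores_row) < 2) stop("need at least 2 class scores")
  s <- sort(scores_row, decreasing = TRUE)
  s[1] - s[2]
}

#' Sparse-representation classification of one sample
#'
#' Codes the (unit-normalized) test vector over the dictionary of training
#' samples by greedy orthogonal matching pursuit with at most
#' \code{n_nonzero} atoms (dictionary atoms are L2-normalized internally),
#' then assigns the class whose atoms' partial reconstruction leaves the
#' smallest residual \eqn{\|x - D_c \delta_c(\alpha)\|_2}. Deterministic;
#' ties break toward the earlier class.
#'
#' @param dictionary n x d matrix of training samples (rows are atoms).
#' @param dict_labels length-n class labels of the atoms.
#' @param x length-d test vector.
#' @param n_nonzero maximum number of atoms in the sparse code.
#' @param classes ordered class set; default order of appearance in
#'   \code{dict_labels}.
#' @return the predicted class label (character scalar).
#' @export
sparse_fallback_classify <- function(dictionary, dict_labels, x,
                                     n_nonzero = 10, classes = NULL) {
  D <- as.matrix(dictionary)
  if (!nrow(D)) stop("empty dictionary")
  dict_labels <- as.character(dict_labels)
  if (is.null(classes)) classes <- unique(dict_labels)
  A <- t(D)                                   # d x n, columns are atoms
  nrm <- sqrt(colSums(A^2))
  nrm[nrm == 0] <- 1
  A <- sweep(A, 2, nrm, "/")
  xn <- as.numeric(x)
  xnorm <- sqrt(sum(xn^2))
  if (xnorm > 0) xn <- xn / xnorm
  n_nonzero <- min(n_nonzero, ncol(A), length(xn))
  support <- integer(0)
  coef <- numeric(0)
  r <- xn
  for (t in seq_len(n_nonzero)) {
    corr <- abs(crossprod(A, r))
    corr[support] <- -Inf
    j <- which.max(corr)                      # ties -> smallest index
    support <- c(support, j)
    As <- A[, support, drop = FALSE]
    coef <- qr.coef(qr(As), xn)
    coef[is.na(coef)] <- 0
    r <- xn - As %*% coef
    if (sqrt(sum(r^2)) < 1e-10) break
  }
  res <- vapply(classes, function(cl) {
    sel <- dict_labels[support] == cl
    approx_c <- if (any(sel))
      A[, support[sel], drop = FALSE] %*% coef[sel] else 0 * xn
    sqrt(sum((xn - approx_c)^2))
  }, numeric(1))
  classes[which.min(res)]
}

#' Hybrid reliability-gated (R)ELM prediction
#'
#' Per test row: if the score-margin \code{\link{reliability}} of the ELM
#' decision is at least \code{threshold}, the ELM argmax label is used;
#' otherwise the row is routed to
#' \code{\link{sparse_fallback_classify}} over the retained training
#' dictionary. \code{threshold = 0} reproduces pure (R)ELM prediction
#' exactly; \code{threshold = Inf} routes every row to the fallback.
#'
#' @param model an \code{elm_model}; must carry a dictionary
#'   (\code{keep_dictionary = TRUE} at training) when \code{threshold > 0}.
#' @param X m x d test matrix.
#' @param threshold non-negative reliability gate.
#' @param n_nonzero sparse-code size for the fallback.
#' @return character vector of predicted labels.
#' @export
predict_hybrid <- function(model, X, threshold = 0, n_nonzero = 10) {
  stopifnot(inherits(model, "elm_model"))
  if (threshold > 0 && is.null(model$dictionary))
    stop("threshold > 0 requires a model trained with keep_dictionary = TRUE")
  S <- predict_scores(model, X)
  labels <- model$classes[apply(S, 1, which.max)]
  if (threshold > 0) {
    margins <- apply(S, 1, reliability)
    unreliable <- which(margins < threshold)
    X <- as.matrix(X)
    for (i in unreliable)
      labels[i] <- sparse_fallback_classify(model$dictionary$X,
                                            model$dictionary$labels,
                                            X[i, ], n_nonzero = n_nonzero,
                                            classes = model$classes)
  }
  labels
}

#' @export
print.elm_model <- function(x, ...) {
  cat("extreme learning machine (", x$activation, ", L = ",
      nrow(x$input_weights), ", C = ", x$C, ")\n", sep = "")
  cat("classes:", paste(x$classes, collapse = "/"),
      if (!is.null(x$dictionary)) " [dictionary retained]", "\n")
  invisible(x)
}
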