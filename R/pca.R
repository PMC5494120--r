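#' Fit a principal-component feature-selection model
#'
#' Computes the top-\code{k} principal axes of the training matrix via SVD
#' of the centered (and, by default, unit-variance scaled) data. Each
#' principal component is a linear combination of the original features;
#' the first covers the maximum variance and each subsequent one the
#' maximum residual variance. Standardization is on by default because
#' regional volumes span very different scales across structures.
#'
#' The sign of each component is fixed so that its largest-magnitude
#' loading is positive, making results deterministic across linear-algebra
#' backends.
#'
#' @param X numeric matrix, n x d, n >= 2.
#' @param k number of components, 1 <= k <= min(n - 1, d).
#' @param standardize divide centered columns by their sample SD.
#' @return an object of class \code{pca_model} with fields \code{mean},
#'   \code{scale}, \code{components} (k x d, orthonormal rows),
#'   \code{explained_variance} (non-increasing), \code{k}.
#' @export
fit_pca <- function(X, k, standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < 2) stop("need at least 2 rows to fit PCA")
  if (k < 1 || k > min(n - 1, d))
    stop("k = ", k, " out of range [1, ", min(n - 1, d), "]")
  mu <- colMeans(X)
  sc <- rep(1, d)
  if (standardize) {
    sc <- apply(X, 2, stats::sd)
    zero <- which(sc <= 0 | !is.finite(sc))
    if (length(zero))
      stop("zero-variance column(s) with standardize = TRUE: ",
           paste(if (!is.null(colnames(X))) colnames(X)[zero] else zero,
                 collapse = ", "))
  }
  Z <- sweep(sweep(X, 2, mu), 2, sc, "/")
  sv <- svd(Z, nu = 0, nv = k)
  comps <- t(sv$v)                       # k x d, orthonormal rows
  for (i in seq_len(k)) {
    j <- which.max(abs(comps[i, ]))
    if (comps[i, j] < 0) comps[i, ] <- -comps[i, ]
  }
  structure(list(mean = mu, scale = sc, components = comps,
                 explained_variance = sv$d[seq_len(k)]^2 / (n - 1),
                 k = as.integer(k), standardize = standardize),
            class = "pca_model")
}

#' Project data onto fitted principal components
#'
#' @param model a \code{\link{fit_pca}} model.
#' @param X m x d matrix with the same feature dimension the model was
#'   fitted on.
#' @return m x k score matrix \code{((X - mean)/scale) \%*\% t(components)}.
#' @export
pca_transform <- function(model, X) {
  stopifnot(inherits(model, "pca_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean))
    stop("X has ", ncol(X), " columns; model expects ", length(model$mean))
  Z <- sweep(sweep(X, 2, model$mean), 2, model$scale, "/")
  Z %*% t(model$components)
}

#' Default grid of component counts
#'
#' The documented search grid for the number of principal components:
#' 2 to 20 in steps of two. When grid search is disabled the documented
#' default is k = 10.
#' @return integer vector \code{c(2, 4, ..., 20)}.
#' @export
default_pca_grid <- function() seq(2L, 20L, by = 2L)

#' Select the number of components by inner cross-validation
#'
#' For every k in the grid, runs an inner stratified k-fold CV in which the
#' PCA model is refit on each inner training fold only (no leakage), the
#' named classifier is trained on the reduced scores, and the mean inner
#' accuracy is recorded. Returns the grid value with the highest mean
#' accuracy, ties broken toward the smaller k. Grid values infeasible for
#' some inner fold (k > min(n_train - 1, d)) are skipped with a warning.
#'
#' @param X n x d matrix. @param labels class labels. @param classifier_spec
#'   classifier name or spec list (see \code{\link{classifier_registry}}).
#' @param grid integer vector of candidate k values.
#' @param inner_folds number of inner stratified folds.
#' @param seed integer seed (inner fold assignment + classifier seeds).
#' @param standardize passed to \code{\link{fit_pca}}.
#' @param classes ordered class set.
#' @return the selected k (integer).
#' @export
select_k <- function(X, labels, classifier_spec = "relm",
                     grid = default_pca_grid(), inner_folds = 5,
                     seed = 1, standardize = TRUE, classes = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (!length(grid)) stop("empty k grid")
  grid <- sort(unique(as.integer(grid)))
  if (length(grid) == 1L) {
    if (grid > min(nrow(X) - 1, ncol(X)))
      stop("k = ", grid, " infeasible for this data")
    return(grid)
  }
  if (is.null(classes)) classes <- unique(labels)
  spec <- as_classifier_spec(classifier_spec)
  folds <- stratified_kfold(labels, k = inner_folds, seed = seed)
  kmax_per_fold <- vapply(seq_len(inner_folds), function(f)
    min(sum(folds != f) - 1L, ncol(X)), integer(1))
  feasible <- grid[grid <= min(kmax_per_fold)]
  if (length(feasible) < length(grid))
    warning("skipping infeasible k values: ",
            paste(setdiff(grid, feasible), collapse = ", "))
  if (!length(feasible)) stop("no feasible k in grid")
  acc <- vapply(feasible, function(k) {
    fold_acc <- vapply(seq_len(inner_folds), function(f) {
      tr <- folds != f
      pm <- fit_pca(X[tr, , drop = FALSE], k, standardize = standardize)
      Ztr <- pca_transform(pm, X[tr, , drop = FALSE])
      Zte <- pca_transform(pm, X[!tr, , drop = FALSE])
      fit <- fit_classifier(spec, Ztr, labels[tr], classes,
                            seed = derive_seed(seed, k, f))
      mean(predict_classifier(fit, Zte) == labels[!tr])
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))
  feasible[which.max(acc)]   # which.max takes the first (smallest) maximizer
}
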