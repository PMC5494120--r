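#' Confusion matrix
#'
#' Rows index the true class, columns the predicted class, both in the
#' declared class order.
#'
#' @param true_labels,predicted_labels equal-length label vectors drawn
#'   from \code{classes}.
#' @param classes ordered class names.
#' @return object of class \code{confusion_matrix}: a K x K integer matrix
#'   with a \code{classes} attribute.
#' @export
confusion <- function(true_labels, predicted_labels, classes) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  bad <- setdiff(unique(c(true_labels, predicted_labels)), classes)
  if (length(bad))
    stop("labels outside the declared class set: ",
         paste(bad, collapse = ", "))
  tt <- table(factor(true_labels, levels = classes),
              factor(predicted_labels, levels = classes))
  m <- matrix(as.integer(tt), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  structure(m, classes = classes, class = c("confusion_matrix", "matrix"))
}

#' Binary accuracy, sensitivity, specificity
#'
#' For a 2x2 confusion matrix with the first class positive:
#' ACC = (TP+TN)/(TP+TN+FP+FN), SEN = TP/(TP+FN), SPE = TN/(TN+FP).
#' A zero denominator yields NaN with a warning.
#'
#' @param cm a 2x2 \code{\link{confusion}} matrix.
#' @return named numeric vector \code{c(acc, sen, spe)} on the 0-1 scale.
#' @export
binary_metrics <- function(cm) {
  if (!all(dim(cm) == 2)) stop("binary_metrics requires a 2x2 matrix")
  tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
  tot <- tp + tn + fp + fn
  acc <- if (tot > 0) (tp + tn) / tot else NaN
  sen <- if (tp + fn > 0) tp / (tp + fn) else NaN
  spe <- if (tn + fp > 0) tn / (tn + fp) else NaN
  if (is.nan(acc) || is.nan(sen) || is.nan(spe))
    warning("zero denominator: metric undefined (NaN)")
  c(acc = acc, sen = sen, spe = spe)
}

#' One-versus-all macro metrics for K classes
#'
#' Accuracy is trace/total. Sensitivity and specificity are computed for
#' each class against the rest (that class positive) and averaged without
#' weighting.
#'
#' @param cm a K x K \code{\link{confusion}} matrix, K >= 2.
#' @return named numeric vector \code{c(acc, sen, spe)} on the 0-1 scale.
#' @export
ova_metrics <- function(cm) {
  K <- nrow(cm)
  if (is.null(K) || K < 2) stop("need a K x K confusion matrix, K >= 2")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  acc <- sum(diag(cm)) / total
  sens <- numeric(K); spes <- numeric(K)
  for (c in seq_len(K)) {
    tp <- cm[c, c]
    fn <- sum(cm[c, ]) - tp
    fp <- sum(cm[, c]) - tp
    tn <- total - tp - fn - fp
    sens[c] <- if (tp + fn > 0) tp / (tp + fn) else NaN
    spes[c] <- if (tn + fp > 0) tn / (tn + fp) else NaN
  }
  c(acc = acc, sen = mean(sens), spe = mean(spes))
}

# ---- SVM baseline (one-vs-all over binary libsvm machines) ------------

#' Fit the SVM baseline
#'
#' Maximum-margin classifier via \pkg{e1071} (libsvm). Binary problems use
#' a single machine; multiclass problems are handled by a one-versus-all
#' reduction: one binary machine per class (that class vs the rest), with
#' prediction by argmax of the decision values.
#'
#' @param X n x d matrix. @param labels class labels (>= 2 classes).
#' @param kernel a \code{\link{kernel_spec}} (\code{"linear"} or
#'   \code{"rbf"}).
#' @param C_svm soft-margin cost.
#' @param classes ordered class set.
#' @return object of class \code{svm_ova_model}.
#' @export
fit_svm <- function(X, labels, kernel = kernel_spec("linear"), C_svm = 1,
                    classes = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (is.null(classes)) classes <- unique(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 classes present")
  if (!is.numeric(C_svm) || C_svm <= 0) stop("C_svm must be > 0")
  kernel <- resolve_gamma(kernel, X)
  ktype <- switch(kernel$name, linear = "linear", rbf = "radial",
                  stop("unsupported SVM kernel '", kernel$name, "'"))
  gamma <- if (kernel$name == "rbf") kernel$gamma else 1 / ncol(X)
  machines <- lapply(classes, function(cl) {
    y <- factor(ifelse(labels == cl, "pos", "rest"),
                levels = c("pos", "rest"))
    if (length(unique(y)) < 2) return(NULL)   # class absent in training
    e1071::svm(X, y, type = "C-classification", kernel = ktype,
               cost = C_svm, gamma = gamma, scale = FALSE)
  })
  structure(list(machines = machines, classes = classes,
                 kernel = kernel, C_svm = C_svm),
            class = "svm_ova_model")
}

#' @export
predict.svm_ova_model <- function(object, X, ...) {
  X <- as.matrix(X)
  dec <- vapply(object$machines, function(m) {
    if (is.null(m)) return(rep(-Inf, nrow(X)))
    d <- attr(stats::predict(m, X, decision.values = TRUE),
              "decision.values")
    # orient so larger = more "pos"
    if (colnames(d)[1] == "pos/rest") as.numeric(d[, 1])
    else -as.numeric(d[, 1])
  }, numeric(nrow(X)))
  dec <- matrix(dec, nrow = nrow(X))
  object$classes[apply(dec, 1, which.max)]
}

# ---- classifier registry ---------------------------------------------

#' Registered classifier specifications
#'
#' Classifiers are addressed by short spec strings throughout the
#' evaluation machinery and the command line:
#' \code{"svm-linear"}, \code{"svm-rbf"}, \code{"klr"}, \code{"ivm"},
#' \code{"elm"}, \code{"relm"}, \code{"relm-hybrid"}.
#' A spec may also be a list \code{list(name = ..., <param> = ...)} whose
#' extra entries override the classifier's default hyperparameters
#' (e.g. \code{list(name = "relm", C = 10, L = 500)}).
#'
#' @return character vector of registered names.
#' @export
classifier_registry <- function() {
  c("svm-linear", "svm-rbf", "klr", "ivm", "elm", "relm", "relm-hybrid")
}

as_classifier_spec <- function(spec) {
  if (is.character(spec)) spec <- list(name = spec)
  if (!is.list(spec) || is.null(spec$name))
    stop("classifier spec must be a name or a list with a $name")
  if (!spec$name %in% classifier_registry())
    stop("unknown classifier '", spec$name, "'; registered: ",
         paste(classifier_registry(), collapse = ", "))
  spec
}

spec_par <- function(spec, key, default) {
  if (!is.null(spec[[key]])) spec[[key]] else default
}

# Inner-CV selection of the KLR/IVM ridge strength (opt-in via
# lambda = "cv").
select_lambda_cv <- function(X, labels, classes, kernel, grid, seed) {
  folds <- stratified_kfold(labels, k = 3, seed = seed)
  acc <- vapply(grid, function(lam) {
    mean(vapply(1:3, function(f) {
      tr <- folds != f
      m <- fit_klr(X[tr, , drop = FALSE], labels[tr], kernel = kernel,
                   lambda = lam, classes = classes)
      mean(predict(m, X[!tr, , drop = FALSE]) == labels[!tr])
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(acc)]
}

# Uniform fit/predict interface over all registered classifiers.
fit_classifier <- function(spec, X, labels, classes, seed = 1) {
  spec <- as_classifier_spec(spec)
  X <- as.matrix(X)
  labels <- as.character(labels)
  lam_default <- 0.01
  model <- switch(spec$name,
    "svm-linear" = fit_svm(X, labels, kernel_spec("linear"),
                           C_svm = spec_par(spec, "C_svm", 1),
                           classes = classes),
    "svm-rbf" = fit_svm(X, labels,
                        kernel_spec("rbf", spec_par(spec, "gamma", NULL)),
                        C_svm = spec_par(spec, "C_svm", 1),
                        classes = classes),
    "klr" = {
      lam <- spec_par(spec, "lambda", lam_default)
      if (identical(lam, "cv"))
        lam <- select_lambda_cv(X, labels, classes,
                                kernel_spec("rbf", spec_par(spec, "gamma", NULL)),
                                10^seq(-3, 1), seed)
      fit_klr(X, labels,
              kernel_spec("rbf", spec_par(spec, "gamma", NULL)),
              lambda = lam, classes = classes)
    },
    "ivm" = {
      lam <- spec_par(spec, "lambda", lam_default)
      if (identical(lam, "cv"))
        lam <- select_lambda_cv(X, labels, classes,
                                kernel_spec("rbf", spec_par(spec, "gamma", NULL)),
                                10^seq(-3, 1), seed)
      fit_ivm(X, labels,
              kernel_spec("rbf", spec_par(spec, "gamma", NULL)),
              lambda = lam,
              epsilon = spec_par(spec, "epsilon", 1e-3),
              delta_t = spec_par(spec, "delta_t", 1L),
              max_import = spec_par(spec, "max_import", 30L),
              greedy_iter = spec_par(spec, "greedy_iter", 1L),
              candidate_sample = spec_par(spec, "candidate_sample", 64L),
              seed = seed, classes = classes)$model
    },
    "elm" = train_elm(X, labels, L = spec_par(spec, "L", NULL), C = Inf,
                      activation = spec_par(spec, "activation", "sigmoid"),
                      seed = seed, classes = classes),
    "relm" = train_elm(X, labels, L = spec_par(spec, "L", NULL),
                       C = spec_par(spec, "C", 1),
                       activation = spec_par(spec, "activation", "sigmoid"),
                       seed = seed, classes = classes),
    "relm-hybrid" = train_elm(X, labels, L = spec_par(spec, "L", NULL),
                              C = spec_par(spec, "C", 1),
                              activation = spec_par(spec, "activation",
                                                    "sigmoid"),
                              seed = seed, classes = classes,
                              keep_dictionary = TRUE))
  structure(list(model = model, spec = spec, classes = classes),
            class = "admorph_classifier")
}

predict_classifier <- function(fit, X) {
  spec <- fit$spec
  if (spec$name == "relm-hybrid")
    predict_hybrid(fit$model, X,
                   threshold = spec_par(spec, "threshold", 0.1),
                   n_nonzero = spec_par(spec, "n_nonzero", 10))
  else predict(fit$model, X)
}

# ---- cross-validation protocols --------------------------------------

# Stratified fold ids 1..k, one per subject; shuffles within class.
stratified_kfold <- function(labels, k, seed) {
  labels <- as.character(labels)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      # shuffle the fold-label multiset so the remainder folds (those
      # receiving one extra subject) differ across classes
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

# Stratified train/test split: fraction `p` of each class to training.
stratified_split <- function(labels, p, seed) {
  labels <- as.character(labels)
  train <- logical(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_tr <- round(p * length(idx))
      n_tr <- max(1L, min(length(idx) - 1L, n_tr))
      train[idx[sample.int(length(idx))][seq_len(n_tr)]] <- TRUE
    }
  })
  train
}

default_repeats <- function(scheme) {
  switch(scheme, split7030 = 100L, kfold10 = 10L, loo = 10L)
}

#' Cross-validated evaluation of a classifier
#'
#' Runs one of three protocols over a feature table: repeated stratified
#' 70/30 train/test splits (\code{"split7030"}, default 100 repeats),
#' repeated stratified 10-fold CV (\code{"kfold10"}, default 10 repeats),
#' or leave-one-out (\code{"loo"}; repetition re-seeds randomized
#' classifiers such as the ELM hidden layer and is otherwise a no-op,
#' default 10 repeats). All model fitting — the PCA reduction, any grid
#' search, and the classifier itself — happens inside the training fold
#' only.
#'
#' For leave-one-out, \code{per_fold} holds one record per held-out
#' subject (n folds of test size 1, accuracy 0 or 100, sen/spe undefined
#' for the single-subject confusion); the aggregate metrics are computed
#' from the confusion matrix pooled over the n predictions of each
#' repeat.
#'
#' @param table a \code{\link{feature_table}}.
#' @param classifier_spec registry name or spec list.
#' @param scheme \code{"split7030"}, \code{"kfold10"} or \code{"loo"}.
#' @param repeats repetition count; \code{NULL} = protocol default.
#' @param seed master seed; folds and classifier seeds derive from it.
#' @param pca PCA configuration:
#'   \code{list(enabled =, k =, grid =, standardize =)}. When
#'   \code{enabled} and \code{grid} is non-NULL, the component count is
#'   re-selected by inner CV inside every training fold; otherwise the
#'   fixed \code{k} (default 10) is used, capped at the training-fold
#'   feasibility limit.
#' @return object of class \code{eval_result}: \code{per_fold} (list of
#'   records with \code{confusion}, \code{acc}, \code{sen}, \code{spe},
#'   percent scale), aggregate \code{mean_acc}, \code{mean_sen},
#'   \code{mean_spe}, \code{sd_acc}, plus protocol metadata.
#' @export
cross_validate <- function(table, classifier_spec, scheme = "kfold10",
                           repeats = NULL, seed = 1,
                           pca = pca_config()) {
  stopifnot(inherits(table, "feature_table"))
  scheme <- match.arg(scheme, c("split7030", "kfold10", "loo"))
  if (is.null(repeats)) repeats <- default_repeats(scheme)
  spec <- as_classifier_spec(classifier_spec)
  labels <- as.character(table$labels)
  classes <- intersect(table$classes, unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes present")
  X <- table$values
  n <- nrow(X)
  per_fold <- list()
  pooled <- list()
  selected_k <- integer(0)

  run_fold <- function(train_idx, test_idx, fold_seed) {
    if (length(unique(labels[train_idx])) < 2)
      stop("training fold contains a single class (seed ", fold_seed, ")")
    Xtr <- X[train_idx, , drop = FALSE]
    Xte <- X[test_idx, , drop = FALSE]
    k_used <- NA_integer_
    if (isTRUE(pca$enabled)) {
      if (!is.null(pca$grid)) {
        k_used <- select_k(Xtr, labels[train_idx], spec, grid = pca$grid,
                           seed = fold_seed, standardize = pca$standardize,
                           classes = classes)
      } else {
        k_used <- min(pca$k, nrow(Xtr) - 1L, ncol(Xtr))
      }
      pm <- fit_pca(Xtr, k_used, standardize = pca$standardize)
      Xte <- pca_transform(pm, Xte)
      Xtr <- pca_transform(pm, Xtr)
    }
    fit <- fit_classifier(spec, Xtr, labels[train_idx], classes,
                          seed = fold_seed)
    list(pred = predict_classifier(fit, Xte), k = k_used)
  }

  fold_record <- function(truth, pred) {
    cm <- confusion(truth, pred, classes)
    met <- if (length(classes) == 2) binary_metrics(cm) else ova_metrics(cm)
    list(confusion = cm, acc = 100 * met[["acc"]],
         sen = 100 * met[["sen"]], spe = 100 * met[["spe"]])
  }

  for (r in seq_len(repeats)) {
    if (scheme == "split7030") {
      sseed <- derive_seed(seed, r, 1)
      train <- stratified_split(labels, 0.7, sseed)
      out <- run_fold(which(train), which(!train), derive_seed(seed, r, 2))
      per_fold[[length(per_fold) + 1L]] <-
        fold_record(labels[!train], out$pred)
      selected_k <- c(selected_k, out$k)
    } else if (scheme == "kfold10") {
      folds <- stratified_kfold(labels, 10L, derive_seed(seed, r, 1))
      for (f in 1:10) {
        if (!any(folds == f)) next          # tiny cohorts: empty test fold
        out <- run_fold(which(folds != f), which(folds == f),
                        derive_seed(seed, r, 1 + f))
        per_fold[[length(per_fold) + 1L]] <-
          fold_record(labels[folds == f], out$pred)
        selected_k <- c(selected_k, out$k)
      }
    } else {                                   # loo
      preds <- character(n)
      for (i in seq_len(n)) {
        out <- run_fold(setdiff(seq_len(n), i), i, derive_seed(seed, r, i))
        preds[i] <- out$pred
        if (i == 1L) selected_k <- c(selected_k, out$k)
      }
      # n single-subject fold records (acc 0/100, sen/spe undefined) plus
      # one pooled record per repeat for the aggregate metrics
      for (i in seq_len(n))
        per_fold[[length(per_fold) + 1L]] <-
          suppressWarnings(fold_record(labels[i], preds[i]))
      pooled[[length(pooled) + 1L]] <- fold_record(labels, preds)
    }
  }
  agg <- if (scheme == "loo") pooled else per_fold
  accs <- vapply(agg, `[[`, numeric(1), "acc")
  sens <- vapply(agg, `[[`, numeric(1), "sen")
  spes <- vapply(agg, `[[`, numeric(1), "spe")
  structure(list(per_fold = per_fold,
                 mean_acc = mean(accs), mean_sen = mean(sens),
                 mean_spe = mean(spes),
                 sd_acc = if (length(accs) > 1) stats::sd(accs) else 0,
                 scheme = scheme, repeats = repeats, seed = seed,
                 classifier = spec$name, classes = classes,
                 selected_k = selected_k[!is.na(selected_k)]),
            class = "eval_result")
}

#' Default PCA configuration for the evaluation pipeline
#'
#' @param enabled apply PCA reduction inside every training fold.
#' @param k fixed component count used when \code{grid} is NULL.
#' @param grid optional grid for per-fold \code{\link{select_k}} search.
#' @param standardize unit-variance scaling before PCA.
#' @return a plain list consumed by \code{\link{cross_validate}}.
#' @export
pca_config <- function(enabled = TRUE, k = 10L, grid = NULL,
                       standardize = TRUE) {
  list(enabled = enabled, k = as.integer(k), grid = grid,
       standardize = standardize)
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("%s / %s: %d fold records over %d repeat(s)\n",
              x$classifier, x$scheme, length(x$per_fold), x$repeats))
  cat(sprintf("ACC %.2f%% (sd %.2f)  SEN %.2f%%  SPE %.2f%%\n",
              x$mean_acc, x$sd_acc, x$mean_sen, x$mean_spe))
  invisible(x)
}

#' Permutation test of cross-validated accuracy
#'
#' Builds the null distribution of the CV statistic (mean accuracy) by
#' repeating the identical cross-validation on label-permuted copies of
#' the data, where the diagnostic labels are randomly shuffled while the
#' feature values stay fixed. The p-value uses the add-one estimator
#' \code{p = (1 + #\{null >= observed\}) / (1 + n_perm)}, which never
#' returns 0.
#'
#' @inheritParams cross_validate
#' @param n_perm number of label permutations, >= 1.
#' @return object of class \code{permutation_result}:
#'   \code{observed_stat} (percent accuracy), \code{null_stats},
#'   \code{p_value}, \code{n_perm}.
#' @export
permutation_test <- function(table, classifier_spec, scheme = "kfold10",
                             repeats = NULL, n_perm = 100, seed = 1,
                             pca = pca_config()) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- cross_validate(table, classifier_spec, scheme, repeats,
                        seed = seed, pca = pca)
  null_stats <- vapply(seq_len(n_perm), function(b) {
    tb <- permute_labels(table, derive_seed(seed, 7, b))
    cross_validate(tb, classifier_spec, scheme, repeats,
                   seed = seed, pca = pca)$mean_acc
  }, numeric(1))
  p <- (1 + sum(null_stats >= obs$mean_acc)) / (1 + n_perm)
  structure(list(observed_stat = obs$mean_acc, null_stats = null_stats,
                 p_value = p, n_perm = n_perm, observed = obs),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("observed accuracy %.2f%%; null mean %.2f%% (n_perm = %d)\n",
              x$observed_stat, mean(x$null_stats), x$n_perm))
  cat(sprintf("p = %.4g\n", x$p_value))
  invisible(x)
}
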