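#' Kernel specification
#'
#' @param name \code{"rbf"} (Gaussian, \eqn{k(x,x') = \exp(-\gamma \|x-x'\|^2)})
#'   or \code{"linear"} (\eqn{k(x,x') = x \cdot x'}).
#' @param gamma positive RBF width; ignored for the linear kernel. The
#'   default \code{NULL} means "derive from the data" as
#'   \code{1 / (d * mean(column variances))} at fit time.
#' @return an object of class \code{kernel_spec}.
#' @export
kernel_spec <- function(name = c("rbf", "linear"), gamma = NULL) {
  name <- match.arg(name)
  if (name == "rbf" && !is.null(gamma) && gamma <= 0)
    stop("gamma must be > 0 for the rbf kernel")
  structure(list(name = name, gamma = gamma), class = "kernel_spec")
}

resolve_gamma <- function(kernel, X) {
  if (kernel$name != "rbf") return(kernel)
  if (is.null(kernel$gamma)) {
    v <- mean(apply(X, 2, stats::var))
    kernel$gamma <- 1 / max(ncol(X) * v, .Machine$double.eps)
  }
  kernel
}

#' Kernel Gram matrix between two point sets
#'
#' @param A p x d matrix. @param B q x d matrix.
#' @param kernel a \code{\link{kernel_spec}} (gamma must be resolved for
#'   rbf).
#' @return p x q matrix with entry (i, j) = k(A_i, B_j); RBF entries lie in
#'   (0, 1] and the matrix is symmetric when A = B.
#' @export
kernel_matrix <- function(A, B, kernel) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B))
    stop("dimension mismatch: ", ncol(A), " vs ", ncol(B), " columns")
  if (kernel$name == "linear") return(A %*% t(B))
  if (is.null(kernel$gamma)) stop("rbf gamma not set; see kernel_spec()")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  exp(-kernel$gamma * d2)
}

# ---- regularized multinomial KLR core ---------------------------------

# One-hot encoding in the declared class order (K columns).
one_hot <- function(labels, classes) {
  f <- factor(as.character(labels), levels = classes)
  if (anyNA(f)) stop("labels outside the declared class set")
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), as.integer(f))] <- 1
  Y
}

# Row-wise softmax of [F, 0] (last class fixed at zero for identifiability).
softmax_probs <- function(F) {
  F <- cbind(F, 0)
  rmax <- F[, 1]
  for (j in 2:ncol(F)) rmax <- pmax(rmax, F[, j])
  E <- exp(F - rmax)
  E / rowSums(E)
}

# theta: (m + 1) x (K - 1); rows 1..m are kernel weights alpha_c, last row
# is the unpenalized bias. Z = [K_nm, 1]. Pen is the m x m penalty matrix
# (Gram or identity); objective
#   Q(theta) = -sum_i log P(y_i | x_i) + (lambda/2) sum_c alpha_c' Pen alpha_c
klr_objective <- function(theta, Z, Y, Pen, lambda) {
  P <- softmax_probs(Z %*% theta)
  nll <- -sum(log(pmax(P[Y == 1], 1e-300)))
  m <- nrow(theta) - 1L
  pen <- 0
  if (m > 0 && lambda > 0) {
    A <- theta[seq_len(m), , drop = FALSE]
    pen <- 0.5 * lambda * sum(A * (Pen %*% A))
  }
  nll + pen
}

klr_gradient <- function(theta, Z, Y, Pen, lambda) {
  K1 <- ncol(theta)
  P <- softmax_probs(Z %*% theta)
  G <- crossprod(Z, P[, seq_len(K1), drop = FALSE] -
                      Y[, seq_len(K1), drop = FALSE])
  m <- nrow(theta) - 1L
  if (m > 0 && lambda > 0)
    G[seq_len(m), ] <- G[seq_len(m), ] +
      lambda * (Pen %*% theta[seq_len(m), , drop = FALSE])
  G
}

# Damped Newton minimization of the convex objective. Returns theta at a
# point with max-abs gradient <= tol, or stops early after max_iter with
# converged = FALSE (callers decide whether that is an error).
klr_newton <- function(theta, Z, Y, Pen, lambda, tol = 1e-6,
                       max_iter = 100L) {
  K1 <- ncol(theta)
  p <- nrow(theta)
  m <- p - 1L
  Q <- klr_objective(theta, Z, Y, Pen, lambda)
  gn <- Inf
  for (it in seq_len(max_iter)) {
    G <- klr_gradient(theta, Z, Y, Pen, lambda)
    gn <- max(abs(G))
    if (gn <= tol) return(list(theta = theta, Q = Q, grad_norm = gn,
                               converged = TRUE, iter = it - 1L))
    P <- softmax_probs(Z %*% theta)
    H <- matrix(0, p * K1, p * K1)
    for (c1 in seq_len(K1)) {
      for (c2 in c1:K1) {
        w <- P[, c1] * ((c1 == c2) - P[, c2])
        B <- crossprod(Z * w, Z)
        if (c1 == c2 && m > 0 && lambda > 0)
          B[seq_len(m), seq_len(m)] <-
            B[seq_len(m), seq_len(m)] + lambda * Pen
        i1 <- (c1 - 1L) * p + seq_len(p)
        i2 <- (c2 - 1L) * p + seq_len(p)
        H[i1, i2] <- B
        if (c1 != c2) H[i2, i1] <- t(B)
      }
    }
    g <- as.vector(G)
    step <- NULL
    jitter <- 0
    for (try in 0:6) {
      ch <- tryCatch(chol(H + diag(jitter, nrow(H))), error = function(e) NULL)
      if (!is.null(ch)) { step <- backsolve(ch, forwardsolve(t(ch), -g)); break }
      jitter <- if (jitter == 0) 1e-8 * (1 + max(abs(diag(H)))) else jitter * 100
    }
    if (is.null(step)) step <- -g   # steepest descent as last resort
    S <- matrix(step, p, K1)
    t_ls <- 1
    repeat {
      cand <- theta + t_ls * S
      Qc <- klr_objective(cand, Z, Y, Pen, lambda)
      if (Qc <= Q + 1e-12 * abs(Q)) { theta <- cand; Q <- Qc; break }
      t_ls <- t_ls / 2
      if (t_ls < 1e-12) break
    }
  }
  list(theta = theta, Q = Q, grad_norm = gn, converged = gn <= tol,
       iter = max_iter)
}

new_klr_model <- function(kernel, reference_points, theta, lambda, classes,
                          penalty) {
  structure(list(kernel = kernel, reference_points = reference_points,
                 weights = theta, lambda = lambda, classes = classes,
                 penalty = penalty),
            class = "klr_model")
}

#' Fit kernel logistic regression
#'
#' Multinomial (softmax) logistic regression in a kernel feature space,
#' with every training point used as a kernel reference point. The
#' regularized negative log-likelihood
#' \deqn{Q(w) = -\log Q_0(w) + (\lambda/2) \sum_c w_c' K w_c}
#' (Gram-matrix penalty, bias unpenalized, last class's weights pinned at
#' zero for identifiability) is minimized by damped Newton-Raphson
#' iteration; the objective is convex, so the optimum is unique in value.
#'
#' @param X n x d training matrix. @param labels class labels (>= 2 classes
#'   present).
#' @param kernel a \code{\link{kernel_spec}}.
#' @param lambda ridge strength, >= 0 (> 0 recommended for rbf).
#' @param tol convergence threshold on the max-abs gradient.
#' @param max_iter Newton iteration cap; non-convergence is an error
#'   carrying the last gradient norm.
#' @param classes ordered class set; defaults to order of appearance.
#' @param penalty \code{"gram"} (w'Kw) or \code{"identity"} (w'w).
#' @return an object of class \code{klr_model}.
#' @export
fit_klr <- function(X, labels, kernel = kernel_spec("rbf"), lambda = 0.01,
                    tol = 1e-6, max_iter = 100L, classes = NULL,
                    penalty = c("gram", "identity")) {
  penalty <- match.arg(penalty)
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (nrow(X) < 2) stop("need at least 2 training points")
  if (is.null(classes)) classes <- unique(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 classes present")
  if (lambda < 0) stop("lambda must be >= 0")
  kernel <- resolve_gamma(kernel, X)
  Y <- one_hot(labels, classes)
  Knn <- kernel_matrix(X, X, kernel)
  Pen <- if (penalty == "gram") Knn else diag(nrow(X))
  Z <- cbind(Knn, 1)
  theta0 <- matrix(0, nrow(X) + 1L, length(classes) - 1L)
  fit <- klr_newton(theta0, Z, Y, Pen, lambda, tol = tol,
                    max_iter = max_iter)
  if (!fit$converged)
    stop("KLR Newton iteration did not converge in ", max_iter,
         " iterations (gradient norm ", signif(fit$grad_norm, 3), ")")
  new_klr_model(kernel, X, fit$theta, lambda, classes, penalty)
}

#' Fit an import vector machine (sparse KLR)
#'
#' Greedy forward selection of a sparse subset of training points — the
#' import vectors — to serve as the kernel reference set of a KLR model.
#' Starting from the empty set (bias-only model), each step adds the
#' candidate training point whose inclusion, with weights refit on the
#' enlarged subset, most decreases the regularized objective \eqn{Q_t}.
#' Selection stops when the relative change
#' \eqn{|Q_t - Q_{t-\Delta t}| / |Q_t|} falls below \code{epsilon}
#' (\code{stopped_reason = "converged"}), when every training point has
#' been included (\code{"exhausted"}), or at \code{max_import}
#' (\code{"max_size"}). With \code{epsilon = 0} and
#' \code{max_import = n} the full KLR model is recovered.
#'
#' Candidate scoring uses a bounded number of warm-started Newton steps
#' (\code{greedy_iter}) for tractability; \code{exact_refit = TRUE}
#' refits every candidate to full convergence (used by the brute-force
#' oracle tests). On large training sets the per-step candidate pool can
#' additionally be restricted to a seeded random subset
#' (\code{candidate_sample}), trading a slightly greedier search for a
#' large constant-factor speedup; the default (\code{NULL}) scores every
#' remaining training point. After a point is accepted the model is
#' always refit to convergence, so the recorded objective trace is
#' non-increasing.
#'
#' @inheritParams fit_klr
#' @param epsilon convergence ratio threshold, >= 0.
#' @param delta_t lag \eqn{\Delta t} in the stopping ratio, >= 1.
#' @param max_import cap on the import-set size; default \code{min(50, n)}.
#' @param greedy_iter Newton steps per candidate evaluation.
#' @param exact_refit refit each candidate to convergence.
#' @param candidate_sample optional cap on the number of candidates scored
#'   per greedy step (seeded random subset); \code{NULL} scores all.
#' @param seed integer seed used only for candidate subsampling.
#' @return list with components \code{model} (a \code{klr_model} whose
#'   reference points are the import vectors only) and \code{report}
#'   (class \code{ivm_report}: \code{import_indices},
#'   \code{objective_trace} including the step-0 bias-only objective,
#'   \code{epsilon_trace}, \code{stopped_reason}).
#' @export
fit_ivm <- function(X, labels, kernel = kernel_spec("rbf"), lambda = 0.01,
                    epsilon = 1e-3, delta_t = 1L,
                    max_import = NULL, greedy_iter = 2L,
                    exact_refit = FALSE, candidate_sample = NULL,
                    seed = 1L, tol = 1e-6, max_iter = 100L,
                    classes = NULL, penalty = c("gram", "identity")) {
  penalty <- match.arg(penalty)
  X <- as.matrix(X)
  labels <- as.character(labels)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 training points")
  if (is.null(classes)) classes <- unique(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 classes present")
  if (epsilon < 0) stop("epsilon must be >= 0")
  delta_t <- as.integer(delta_t)
  if (delta_t < 1) stop("delta_t must be >= 1")
  if (is.null(max_import)) max_import <- min(50L, n)
  max_import <- min(as.integer(max_import), n)
  kernel <- resolve_gamma(kernel, X)
  Y <- one_hot(labels, classes)
  K1 <- length(classes) - 1L
  Knn <- kernel_matrix(X, X, kernel)
  use_gram <- penalty == "gram"

  # bias-only start (empty import set)
  fit0 <- klr_newton(matrix(0, 1L, K1), matrix(1, n, 1L),
                     Y, matrix(0, 0, 0), lambda, tol = tol,
                     max_iter = max_iter)
  theta <- fit0$theta
  S <- integer(0)
  q_trace <- fit0$Q
  eps_trace <- numeric(0)
  reason <- "exhausted"

  refit <- function(cols, th0, full) {
    Zs <- cbind(Knn[, cols, drop = FALSE], 1)
    Pen <- if (use_gram) Knn[cols, cols, drop = FALSE]
           else diag(length(cols))
    klr_newton(th0, Zs, Y, Pen, lambda, tol = tol,
               max_iter = if (full) max_iter else as.integer(greedy_iter))
  }

  while (length(S) < max_import) {
    cand <- setdiff(seq_len(n), S)
    if (!is.null(candidate_sample) && length(cand) > candidate_sample) {
      pick <- with_seed(derive_seed(seed, length(S)),
                        sample.int(length(cand), candidate_sample))
      cand <- sort(cand[pick])
    }
    m <- length(S)
    # warm start: previous weights with a zero row for the new point
    th_warm <- rbind(theta[seq_len(m), , drop = FALSE],
                     matrix(0, 1L, K1),
                     theta[m + 1L, , drop = FALSE])
    qs <- vapply(cand, function(j) {
      refit(c(S, j), th_warm, full = exact_refit)$Q
    }, numeric(1))
    j_best <- cand[which.min(qs)]
    S <- c(S, j_best)
    fit <- refit(S, th_warm, full = TRUE)
    if (!fit$converged)
      stop("IVM refit did not converge (import set size ", length(S),
           ", gradient norm ", signif(fit$grad_norm, 3), ")")
    theta <- fit$theta
    q_trace <- c(q_trace, fit$Q)
    t_now <- length(q_trace)          # index of Q_t (1-based, step 0 first)
    if (t_now - delta_t >= 1) {
      ratio <- abs(q_trace[t_now] - q_trace[t_now - delta_t]) /
               max(abs(q_trace[t_now]), .Machine$double.eps)
      eps_trace <- c(eps_trace, ratio)
      if (ratio < epsilon) { reason <- "converged"; break }
    }
  }
  if (reason != "converged" && length(S) >= max_import && max_import < n)
    reason <- "max_size"
  model <- new_klr_model(kernel, X[S, , drop = FALSE], theta, lambda,
                         classes, penalty)
  report <- structure(list(import_indices = S, objective_trace = q_trace,
                           epsilon_trace = eps_trace,
                           stopped_reason = reason),
                      class = "ivm_report")
  list(model = model, report = report)
}

#' Posterior class probabilities from a KLR/IVM model
#'
#' @param model a \code{klr_model}. @param X m x d matrix.
#' @return m x K row-stochastic matrix (columns in the model's class
#'   order); rows sum to 1.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "klr_model"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$reference_points))
    stop("X has ", ncol(X), " columns; model expects ",
         ncol(model$reference_points))
  Kx <- kernel_matrix(X, model$reference_points, model$kernel)
  P <- softmax_probs(cbind(Kx, 1) %*% model$weights)
  colnames(P) <- model$classes
  P
}

#' Predicted class labels (argmax of the posterior)
#'
#' Ties are broken toward the earlier class in the declared order.
#' @param object a \code{klr_model}. @param X m x d matrix.
#' @param ... unused.
#' @return character vector of class labels.
#' @export
predict.klr_model <- function(object, X, ...) {
  P <- predict_proba(object, X)
  object$classes[apply(P, 1, which.max)]
}

#' @export
print.klr_model <- function(x, ...) {
  cat("kernel logistic regression model (", x$kernel$name, " kernel)\n",
      sep = "")
  cat("reference points:", nrow(x$reference_points),
      " lambda:", x$lambda, " classes:",
      paste(x$classes, collapse = "/"), "\n")
  invisible(x)
}
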