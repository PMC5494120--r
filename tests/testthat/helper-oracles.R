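# Independent oracles used across the suite. These recompute quantities
# from first principles (dist(), eigen(), optim(), explicit loops) and
# deliberately share no code with the package's own fitting paths.

# RBF Gram matrix via dist(); linear via tcrossprod.
oracle_kernel <- function(A, B, name = "rbf", gamma = 1) {
  if (name == "linear") return(A %*% t(B))
  d2 <- as.matrix(stats::dist(rbind(A, B)))^2
  d2 <- d2[seq_len(nrow(A)), nrow(A) + seq_len(nrow(B)), drop = FALSE]
  exp(-gamma * d2)
}

# Regularized multinomial KLR objective evaluated from scratch.
# theta_vec stacks (K-1) columns of length (m_ref + 1); reference points
# given explicitly so the same function serves full KLR and IVM subsets.
oracle_klr_objective <- function(theta_vec, X, y_int, K, ref, gamma,
                                 lambda) {
  m <- nrow(ref)
  Th <- matrix(theta_vec, m + 1L, K - 1L)
  Kx <- oracle_kernel(X, ref, "rbf", gamma)
  F <- cbind(Kx %*% Th[seq_len(m), , drop = FALSE] +
               matrix(Th[m + 1L, ], nrow(X), K - 1L, byrow = TRUE), 0)
  nll <- 0
  for (i in seq_len(nrow(X))) {
    z <- F[i, ] - max(F[i, ])
    nll <- nll - (z[y_int[i]] - log(sum(exp(z))))
  }
  Krr <- oracle_kernel(ref, ref, "rbf", gamma)
  pen <- 0
  for (c in seq_len(K - 1L))
    pen <- pen + 0.5 * lambda *
      sum(Th[seq_len(m), c] * (Krr %*% Th[seq_len(m), c]))
  nll + pen
}

# Minimum of the KLR objective by a general-purpose quasi-Newton optimizer.
oracle_klr_optim <- function(X, y_int, K, gamma, lambda, ref = X) {
  p <- (nrow(ref) + 1L) * (K - 1L)
  fit <- stats::optim(rep(0, p), oracle_klr_objective,
                      X = X, y_int = y_int, K = K, ref = ref,
                      gamma = gamma, lambda = lambda,
                      method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-14))
  fit$value
}

# Minimum-norm least squares via MASS::ginv (plain ELM oracle).
oracle_lstsq <- function(H, Tm) MASS::ginv(H) %*% Tm

# Ridge solution via an augmented least-squares system (RELM oracle):
# minimizes ||H b - T||^2 + ||b||^2 / C.
oracle_ridge <- function(H, Tm, C) {
  L <- ncol(H)
  Ha <- rbind(H, diag(sqrt(1 / C), L))
  Ta <- rbind(Tm, matrix(0, L, ncol(Tm)))
  qr.solve(Ha, Ta)
}

# Brute-force confusion tally + metric formulas by explicit loops.
oracle_confusion <- function(truth, pred, classes) {
  K <- length(classes)
  m <- matrix(0L, K, K)
  for (i in seq_along(truth))
    m[match(truth[i], classes), match(pred[i], classes)] <-
      m[match(truth[i], classes), match(pred[i], classes)] + 1L
  m
}

oracle_ova <- function(cm) {
  K <- nrow(cm); total <- sum(cm)
  sens <- spes <- numeric(K)
  for (c in seq_len(K)) {
    tp <- cm[c, c]; fn <- sum(cm[c, ]) - tp; fp <- sum(cm[, c]) - tp
    tn <- total - tp - fn - fp
    sens[c] <- tp / (tp + fn); spes[c] <- tn / (tn + fp)
  }
  c(acc = sum(diag(cm)) / total, sen = mean(sens), spe = mean(spes))
}

# Small labelled Gaussian-blob problem used by several classifier tests.
make_blobs <- function(n_per = 20, d = 2, sep = 4, K = 2, seed = 1) {
  set.seed(seed)
  centers <- matrix(0, K, d)
  for (k in seq_len(K)) centers[k, 1 + (k - 1) %% d] <- (k - 1) * sep
  X <- do.call(rbind, lapply(seq_len(K), function(k)
    sweep(matrix(rnorm(n_per * d), n_per, d), 2, centers[k, ], "+")))
  list(X = X, y = rep(LETTERS[seq_len(K)], each = n_per),
       classes = LETTERS[seq_len(K)])
}

# FreeSurfer-style stats fixture writer (aseg dialect).
write_fs_stats <- function(path, structures, volumes,
                           col_headers = TRUE) {
  lines <- c("# Title Segmentation Statistics",
             "# generator synthetic fixture")
  if (col_headers)
    lines <- c(lines,
               "# ColHeaders Index SegId NVoxels Volume_mm3 StructName normMean")
  for (i in seq_along(structures))
    lines <- c(lines, sprintf("%3d %4d %6d %9.1f %s %8.4f",
                              i, 10 + i, round(volumes[i]), volumes[i],
                              structures[i], 95.5))
  writeLines(lines, path)
  path
}
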