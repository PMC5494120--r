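#' Specification of a synthetic three-class morphometric cohort
#'
#' Describes a cohort of NC/MCI/AD subjects with Gaussian regional-volume
#' features. A subset of "affected" features carries a class-ordered mean
#' reduction (NC > MCI > AD), emulating staged grey-matter atrophy: for a
#' subject at disease stage \eqn{s} (NC = 0, MCI = 1, AD = 2) an affected
#' feature has mean \code{baseline_mean - s * effect * noise_sd}. Unaffected
#' features are class-independent. Noise is Gaussian with standard
#' deviation \code{noise_sd} and optional equicorrelation \code{correlation}
#' across features.
#'
#' Defaults mirror the cohort composition and dimensionality this package
#' is designed around: 70 NC / 74 MCI / 70 AD subjects and 54 regional
#' volume features, of which 12 are disease-sensitive. \code{baseline_mean}
#' of 5000 mm^3 with \code{noise_sd} 500 mm^3 (a 10\% coefficient of
#' variation) is typical of subcortical structure volumes.
#'
#' @param n_per_class integer vector of subjects per class, NC/MCI/AD order.
#' @param n_features total number of features.
#' @param n_affected number of class-sensitive features (the first
#'   \code{n_affected} columns).
#' @param effect atrophy step per disease stage, in units of
#'   \code{noise_sd} (unit-free standardized effect size); 0 gives a null
#'   cohort with no class signal.
#' @param noise_sd within-class standard deviation per feature (mm^3).
#' @param baseline_mean healthy-control mean per feature (mm^3); scalar or
#'   length-\code{n_features} vector.
#' @param correlation equicorrelation rho among features, |rho| < 1.
#' @param seed integer seed; the cohort is a pure function of the spec.
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_per_class = c(70, 74, 70), n_features = 54,
                        n_affected = min(12, n_features), effect = 1,
                        noise_sd = 500,
                        baseline_mean = 5000, correlation = 0, seed = 1) {
  if (length(n_per_class) != 3 || any(n_per_class < 0))
    stop("n_per_class must be three non-negative counts (NC, MCI, AD)")
  if (n_features < 0 || n_affected < 0 || n_affected > n_features)
    stop("need 0 <= n_affected <= n_features")
  if (effect < 0) stop("effect must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (abs(correlation) >= 1) stop("|correlation| must be < 1")
  if (!length(baseline_mean) %in% c(1L, n_features))
    stop("baseline_mean must be scalar or length n_features")
  structure(list(n_per_class = as.integer(n_per_class),
                 n_features = as.integer(n_features),
                 n_affected = as.integer(n_affected),
                 effect = effect, noise_sd = noise_sd,
                 baseline_mean = baseline_mean,
                 correlation = correlation, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws the cohort described by a \code{\link{cohort_spec}}. Equicorrelated
#' noise uses the one-factor construction
#' \eqn{x = \sqrt{1-\rho}\, e + \sqrt{\rho}\, g} with a shared per-subject
#' factor \eqn{g}, which yields exactly the equicorrelation matrix
#' \eqn{(1-\rho) I + \rho J} for \eqn{\rho \ge 0} (negative \eqn{\rho} is
#' rejected at generation; it is not representable by a common factor).
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return a \code{\link{feature_table}} with
#'   \code{sum(spec$n_per_class)} rows and class labels NC/MCI/AD.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$correlation < 0)
    stop("negative equicorrelation is not supported by the one-factor model")
  classes <- c("NC", "MCI", "AD")
  n <- sum(spec$n_per_class)
  d <- spec$n_features
  labels <- rep(classes, times = spec$n_per_class)
  stage <- rep(0:2, times = spec$n_per_class)
  base <- rep(spec$baseline_mean, length.out = d)
  mu <- matrix(rep(base, each = n), n, d)
  if (spec$n_affected > 0 && spec$effect > 0) {
    aff <- seq_len(spec$n_affected)
    mu[, aff] <- mu[, aff] - outer(stage, rep(spec$effect * spec$noise_sd,
                                              spec$n_affected))
  }
  vals <- with_seed(spec$seed, {
    e <- matrix(stats::rnorm(n * d), n, d)
    if (spec$correlation > 0) {
      g <- stats::rnorm(n)
      e <- sqrt(1 - spec$correlation) * e + sqrt(spec$correlation) * g
    }
    mu + spec$noise_sd * e
  })
  feature_table(vals, labels,
                subject_ids = sprintf("syn%03d", seq_len(n)),
                feature_names = sprintf("roi%02d", seq_len(d)),
                classes = classes)
}

#' Randomly permute the class labels of a table
#'
#' The permutation-test primitive: values and subject ids are untouched,
#' the label multiset is conserved, and the permutation is uniform over all
#' orderings and reproducible from \code{seed}.
#'
#' @param table a \code{\link{feature_table}} with at least 2 subjects.
#' @param seed integer seed.
#' @return a \code{\link{feature_table}} with permuted labels.
#' @export
permute_labels <- function(table, seed) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$values)
  if (n < 2) stop("need at least 2 subjects to permute labels")
  perm <- with_seed(seed, sample.int(n))
  feature_table(table$values, as.character(table$labels)[perm],
                subject_ids = table$subject_ids,
                feature_names = table$feature_names,
                classes = table$classes)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards. All package randomness funnels through this.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic fan-out of a master seed into per-stage streams; keeps all
# derived seeds in 32-bit range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 48271 + as.double(k) * 16807 + 1) %% 2147483647
  as.integer(s)
}
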