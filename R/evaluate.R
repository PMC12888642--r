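#' Shared stratified fold plan for a federated cohort
#'
#' Assigns every row of every site to exactly one of `k` folds, stratified
#' by label within each site (per fold and site the class counts are within
#' one sample of an exactly proportional split). The same plan serves the
#' per-site models and the pooled general model: the general model's fold-i
#' test set is the union over sites of each site's fold i.
#'
#' @param cohort a [federated_cohort()].
#' @param k fold count (default 5).
#' @param seed integer seed; the plan is a deterministic function of it.
#' @return an object of class `fold_plan`: `k`, `seed`, and `assignments`, a
#'   named list (per site) of integer fold ids.
#' @export
build_fold_plan <- function(cohort, k = 5L, seed = 1L) {
  stopifnot(inherits(cohort, "federated_cohort"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  seeds <- derive_seeds(seed, length(cohort$sites))
  assignments <- vector("list", length(cohort$sites))
  names(assignments) <- names(cohort$sites)
  for (i in seq_along(cohort$sites)) {
    assignments[[i]] <- stratified_fold_ids(cohort$sites[[i]]$labels, k,
                                            seeds[i])
  }
  structure(list(k = k, seed = as.integer(seed), assignments = assignments),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> k = %d over %d sites (seed %d)\n",
              x$k, length(x$assignments), x$seed))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with midrank tie handling: the
#' probability that a random positive's score exceeds a random negative's,
#' ties counted one half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (both classes must be present).
#' @return scalar in `[0, 1]`.
#' @examples
#' auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-index operating point
#'
#' Sweeps every observed score as a candidate threshold (samples scoring at
#' or above the threshold are called positive) and returns the threshold
#' maximizing the Youden index `J = sensitivity + specificity - 1`. On ties
#' in `J`, the lowest qualifying threshold is returned.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (both classes present).
#' @return an object of class `operating_point`: `threshold`, `sensitivity`,
#'   `specificity`, `youden`.
#' @export
youden_operating_point <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  thr <- sort(unique(scores))
  # decreasing thresholds: cumulative counts of scores >= t
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0L) / n0,
                 numeric(1))
  j <- sens + spec - 1
  # ties in J (within numerical tolerance) break to the lowest threshold;
  # thr is sorted ascending, so the first qualifying index is the lowest
  best <- which(j >= max(j) - 1e-12)[1L]
  structure(
    list(threshold = thr[best], sensitivity = sens[best],
         specificity = spec[best], youden = j[best]),
    class = "operating_point"
  )
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf(
    "<operating_point> threshold %.4f: sensitivity %.3f, specificity %.3f\n",
    x$threshold, x$sensitivity, x$specificity
  ))
  invisible(x)
}

#' Summarize fold-wise AUROCs
#'
#' Mean with a normal-approximation 95% confidence interval across folds,
#' `mean +/- 1.96 * sd / sqrt(k)`, clipped to `[0, 1]`.
#'
#' @param per_fold_aurocs numeric vector of at least two fold AUROCs.
#' @return list `mean`, `ci_lo`, `ci_hi`.
#' @examples
#' summarize_folds(c(0.7, 0.8, 0.9))
#' @export
summarize_folds <- function(per_fold_aurocs) {
  stopifnot(is.numeric(per_fold_aurocs), !anyNA(per_fold_aurocs))
  k <- length(per_fold_aurocs)
  if (k < 2L) stop("at least two folds are required")
  m <- mean(per_fold_aurocs)
  half <- 1.96 * stats::sd(per_fold_aurocs) / sqrt(k)
  list(mean = m, ci_lo = max(0, m - half), ci_hi = min(1, m + half))
}
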