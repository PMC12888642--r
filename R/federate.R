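#' Federated ensemble of per-site forests
#'
#' Per-site models plus an aligned [normalize_weights()] weight vector. The
#' "central server" of a federated deployment is simulated in-process: the
#' ensemble holds the transferred models and aggregates their predicted
#' probabilities.
#'
#' @param models list of [train_local_forest()] models (or anything with a
#'   [predict_probability()] method and a `site_id`), one per site.
#' @param weights a `weight_vector` whose site order matches `models`.
#' @return an object of class `federated_ensemble`.
#' @export
federated_ensemble <- function(models, weights) {
  stopifnot(is.list(models), length(models) >= 1L,
            inherits(weights, "weight_vector"))
  ids <- unname(vapply(models, `[[`, character(1), "site_id"))
  if (!identical(ids, unname(weights$site_id))) {
    stop("weight vector site order does not match the models")
  }
  structure(list(models = models, weights = weights),
            class = "federated_ensemble")
}

#' @export
print.federated_ensemble <- function(x, ...) {
  cat(sprintf("<federated_ensemble> %d site models, scheme = %s\n",
              length(x$models), x$weights$scheme))
  invisible(x)
}

#' Weighted-average federated prediction
#'
#' The federated probability for each sample is the convex combination
#' `P = sum_i w_i * x_i` of the per-site model probabilities `x_i` under the
#' ensemble's weight vector; it always lies between the smallest and largest
#' per-site probability.
#'
#' @param ensemble a [federated_ensemble()].
#' @param features data.frame conforming to the shared feature schema.
#' @return numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
federated_predict <- function(ensemble, features) {
  stopifnot(inherits(ensemble, "federated_ensemble"))
  w <- ensemble$weights$weights
  probs <- site_probability_matrix(ensemble$models, features)
  drop(probs %*% w)
}

# n x n_sites matrix of per-site model probabilities
#' @keywords internal
site_probability_matrix <- function(models, features) {
  features <- as.data.frame(features)
  vapply(models, predict_probability, numeric(nrow(features)),
         features = features)
}

#' Unweighted (mean) federated prediction
#'
#' The baseline federated model: the plain mean over site models of each
#' model's predicted probability — [federated_predict()] with equal weights
#' `1/N`.
#'
#' @param models list of per-site models.
#' @param features data.frame conforming to the shared schema.
#' @return numeric vector of probabilities, one per row.
#' @export
unweighted_predict <- function(models, features) {
  stopifnot(is.list(models), length(models) >= 1L)
  probs <- site_probability_matrix(models, features)
  rowMeans(probs)
}

#' Prediction of the pooled union-of-trees forest
#'
#' Treats all trees of all site forests as one forest in which each tree of
#' site `i` (with `m_i` trees) carries weight `1 / (N * m_i)`, and returns
#' the weighted mean of per-tree terminal-node positive frequencies. This is
#' algebraically identical to [unweighted_predict()] — the equivalence that
#' lets prediction averaging stand in for physically merging forests — and
#' reduces to the plain unweighted mean over the pooled trees when all sites
#' grew the same number of trees.
#'
#' @param models list of `local_forest` models sharing one schema.
#' @param features data.frame conforming to that schema.
#' @return numeric vector of probabilities, one per row.
#' @export
pooled_forest_predict <- function(models, features) {
  stopifnot(is.list(models), length(models) >= 1L)
  features <- as.data.frame(features)
  n_sites <- length(models)
  acc <- numeric(nrow(features))
  for (m in models) {
    tp <- per_tree_probability(m, features)
    acc <- acc + rowSums(tp) / (n_sites * m$ntree)
  }
  acc
}
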