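#' Hyper-parameter grid for per-site forests
#'
#' @param ntree_values candidate tree counts. The full published protocol
#'   uses `seq(100, 1000, by = 100)`; the desk-scale default is
#'   `c(100, 300, 500)`.
#' @param mtry_values candidate per-split feature counts. Full protocol:
#'   `1:30`; desk-scale default: a band of width 2 around `floor(sqrt(d))`,
#'   built by [default_grid()].
#' @return an object of class `hyper_grid`.
#' @export
hyper_grid <- function(ntree_values = c(100L, 300L, 500L),
                       mtry_values = 4:8) {
  ntree_values <- as.integer(ntree_values)
  mtry_values <- as.integer(mtry_values)
  stopifnot(length(ntree_values) >= 1L, length(mtry_values) >= 1L,
            all(ntree_values >= 1L), all(mtry_values >= 1L))
  structure(list(ntree_values = ntree_values, mtry_values = mtry_values),
            class = "hyper_grid")
}

#' Desk-scale default grid for a `d`-dimensional feature space
#'
#' `ntree` in \{100, 300, 500\} and `mtry` spanning `floor(sqrt(d)) - 2` to
#' `floor(sqrt(d)) + 2` (clipped to `[1, d]`). `full = TRUE` returns the
#' full published tuning range instead: `ntree` 100-1000 by 100, `mtry` 1-30.
#'
#' @param d feature dimension.
#' @param full use the full tuning range.
#' @return a [hyper_grid()].
#' @export
default_grid <- function(d, full = FALSE) {
  if (full) return(hyper_grid(seq(100L, 1000L, by = 100L), 1:30))
  m <- floor(sqrt(d))
  hyper_grid(c(100L, 300L, 500L), max(1L, m - 2L):min(d, m + 2L))
}

#' Inner cross-validation specification for tuning
#'
#' Repeated stratified k-fold CV run inside the training data only; the
#' tuning metric is classification accuracy at the 0.5 probability cutoff.
#' The published protocol uses 5 repeats of 10-fold CV.
#'
#' @param repeats number of CV repetitions (>= 1).
#' @param folds folds per repetition (>= 2).
#' @param seed integer seed controlling fold assignment and forest growth.
#' @return an object of class `inner_cv_spec`.
#' @export
inner_cv_spec <- function(repeats = 5L, folds = 10L, seed = 1L) {
  stopifnot(repeats >= 1L, folds >= 2L)
  structure(list(repeats = as.integer(repeats), folds = as.integer(folds),
                 metric = "accuracy", seed = as.integer(seed)),
            class = "inner_cv_spec")
}

#' Tune forest hyper-parameters by repeated stratified inner CV
#'
#' Grid search over `(ntree, mtry)`: each cell is scored by its mean accuracy
#' (0.5 probability cutoff) across `repeats x folds` stratified inner splits
#' of the training cohort, and the best cell is returned. Tuning touches only
#' `train`; the selection therefore never depends on any test fold. `mtry`
#' values exceeding the feature dimension are clipped (with a warning). A
#' one-cell grid is returned immediately, without running any CV.
#'
#' @param train a [site_cohort()] containing both classes.
#' @param grid a [hyper_grid()].
#' @param spec an [inner_cv_spec()].
#' @param details also return the per-cell accuracy table and the inner fold
#'   assignments (for audit).
#' @return list with `ntree`, `mtry`; with `details = TRUE` also `accuracy`
#'   (data.frame ntree, mtry, accuracy) and `fold_ids` (repeats x n matrix).
#' @export
tune_hyperparameters <- function(train, grid, spec = inner_cv_spec(),
                                 details = FALSE) {
  stopifnot(inherits(train, "site_cohort"), inherits(grid, "hyper_grid"),
            inherits(spec, "inner_cv_spec"))
  if (length(unique(train$labels)) < 2L) {
    stop("tuning requires both classes in the training data")
  }
  d <- ncol(train$features)
  mtry_values <- grid$mtry_values
  if (any(mtry_values > d)) {
    warning("mtry values exceeding the feature dimension (", d, ") were clipped")
    mtry_values <- sort(unique(pmin(mtry_values, d)))
  }
  cells <- expand.grid(ntree = grid$ntree_values, mtry = mtry_values,
                       KEEP.OUT.ATTRS = FALSE)
  if (nrow(cells) == 1L) {
    out <- list(ntree = cells$ntree[1L], mtry = cells$mtry[1L])
    if (details) {
      out$accuracy <- cbind(cells, accuracy = NA_real_)
      out$fold_ids <- NULL
    }
    return(out)
  }

  seeds <- derive_seeds(spec$seed, spec$repeats + 1L)
  fold_ids <- vapply(seq_len(spec$repeats), function(r) {
    stratified_fold_ids(train$labels, spec$folds, seeds[r])
  }, integer(length(train$labels)))

  acc <- matrix(NA_real_, nrow = nrow(cells),
                ncol = spec$repeats * spec$folds)
  col <- 0L
  for (r in seq_len(spec$repeats)) {
    for (f in seq_len(spec$folds)) {
      col <- col + 1L
      hold <- fold_ids[, r] == f
      fit_dat <- list(features = train$features[!hold, , drop = FALSE],
                      labels = train$labels[!hold])
      for (ci in seq_len(nrow(cells))) {
        rf <- fit_forest(fit_dat$features, fit_dat$labels,
                         ntree = cells$ntree[ci], mtry = cells$mtry[ci],
                         seed = seeds[spec$repeats + 1L])
        p <- forest_prob(rf, train$features[hold, , drop = FALSE])
        acc[ci, col] <- mean(as.integer(p >= 0.5) == train$labels[hold])
      }
    }
  }
  mean_acc <- rowMeans(acc)
  best <- which.max(mean_acc)  # ties: first cell in grid order
  out <- list(ntree = cells$ntree[best], mtry = cells$mtry[best])
  if (details) {
    out$accuracy <- cbind(cells, accuracy = mean_acc)
    out$fold_ids <- fold_ids
  }
  out
}

# ranger probability forest: its per-sample prediction is exactly the mean
# over trees of the terminal node's positive-class relative frequency.
#' @keywords internal
fit_forest <- function(features, labels, ntree, mtry, seed) {
  y <- factor(labels, levels = c(0L, 1L))
  dat <- cbind(features, .y = y)
  suppressWarnings(ranger::ranger(
    dependent.variable.name = ".y", data = dat,
    num.trees = ntree, mtry = min(mtry, ncol(features)),
    probability = TRUE, seed = seed, num.threads = 1L,
    respect.unordered.factors = "ignore"
  ))
}

# Positive-class probability from a fitted ranger probability forest; robust
# to single-class training data (dropped factor level).
#' @keywords internal
forest_prob <- function(rf, features, predict_all = FALSE) {
  pr <- stats::predict(rf, data = features, num.threads = 1L,
                       predict.all = predict_all)$predictions
  if (predict_all) {
    cls <- dimnames(pr)[[2]]
    if (!"1" %in% cls) return(matrix(0, nrow = dim(pr)[1], ncol = dim(pr)[3]))
    return(pr[, "1", , drop = TRUE])
  }
  if (!"1" %in% colnames(pr)) return(rep(0, nrow(pr)))
  unname(pr[, "1"])
}

#' Train one site's random forest
#'
#' Grows a probability forest of exactly `ntree` trees (CART splits, Gini
#' impurity, bootstrap resampling, no depth limit) whose per-sample
#' positive-class probability is the mean over trees of the terminal node's
#' positive-class relative frequency. Deterministic given `seed`. Training
#' data with a single class is allowed (with a warning): the forest then
#' predicts that class's probability (0 or 1) for every input.
#'
#' @param train a [site_cohort()].
#' @param ntree number of trees.
#' @param mtry candidate features per split (clipped to the feature count).
#' @param seed integer seed for forest growth.
#' @return an object of class `local_forest`.
#' @export
train_local_forest <- function(train, ntree, mtry, seed = 1L) {
  stopifnot(inherits(train, "site_cohort"), ntree >= 1L, mtry >= 1L)
  if (length(unique(train$labels)) < 2L) {
    warning("site ", train$site_id,
            " has single-class training labels; predictions will be constant")
  }
  rf <- fit_forest(train$features, train$labels, ntree, mtry, seed)
  structure(
    list(site_id = train$site_id, ntree = as.integer(ntree),
         mtry = as.integer(min(mtry, ncol(train$features))),
         schema = train$schema, seed = as.integer(seed), forest = rf),
    class = "local_forest"
  )
}

#' @export
print.local_forest <- function(x, ...) {
  cat(sprintf("<local_forest> %s: ntree = %d, mtry = %d, d = %d\n",
              x$site_id, x$ntree, x$mtry, length(x$schema$names)))
  invisible(x)
}

#' Positive-class probability of a trained model
#'
#' For a `local_forest`, the mean over its trees of the terminal-node
#' positive-class relative frequency, vectorized over samples.
#'
#' @param model a trained model.
#' @param features data.frame conforming to the model's feature schema.
#' @return numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predict_probability <- function(model, features) {
  UseMethod("predict_probability")
}

#' @rdname predict_probability
#' @export
predict_probability.local_forest <- function(model, features) {
  features <- as.data.frame(features)
  check_schema(features, model$schema)
  forest_prob(model$forest, features)
}

#' Per-tree terminal-node positive-class frequencies
#'
#' The per-tree decomposition of a forest's probability: an
#' `n x ntree` matrix whose row means equal [predict_probability()].
#'
#' @param model a `local_forest`.
#' @param features data.frame conforming to the model's schema.
#' @return numeric matrix, samples by trees.
#' @export
per_tree_probability <- function(model, features) {
  stopifnot(inherits(model, "local_forest"))
  features <- as.data.frame(features)
  check_schema(features, model$schema)
  out <- forest_prob(model$forest, features, predict_all = TRUE)
  matrix(out, nrow = nrow(features), ncol = model$ntree)
}
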