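#' Feature schema of a federated cohort
#'
#' In horizontal federated learning every site holds different patients but
#' the same feature space. A `feature_schema` fixes that space: an ordered set
#' of unique feature names, each tagged `"binary"` or `"continuous"`.
#'
#' @param names character vector of unique feature names (order is fixed).
#' @param kinds character vector, one of `"binary"`, `"continuous"` per feature.
#' @return an object of class `feature_schema` with elements `names`, `kinds`.
#' @examples
#' feature_schema(c("age", "icd_f05"), c("continuous", "binary"))
#' @export
feature_schema <- function(names, kinds) {
  stopifnot(is.character(names))
  if (anyDuplicated(names)) stop("feature names must be unique")
  kinds <- as.character(kinds)
  if (!all(kinds %in% c("binary", "continuous"))) {
    stop("kinds must be 'binary' or 'continuous'")
  }
  if (length(kinds) != length(names)) stop("one kind per feature name required")
  structure(list(names = names, kinds = kinds), class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf(
    "<feature_schema> %d features (%d binary, %d continuous)\n",
    length(x$names), sum(x$kinds == "binary"), sum(x$kinds == "continuous")
  ))
  invisible(x)
}

#' One site's cohort: feature table plus binary labels
#'
#' The unit of horizontal partitioning: one hospital's (or site's) feature
#' table and its binary outcome labels (1 = positive case, e.g. delirium).
#'
#' @param site_id short site label, e.g. `"H01"`.
#' @param features data.frame of features, one row per sample.
#' @param labels integer/numeric vector of 0/1 labels, one per row of
#'   `features`.
#' @param schema optional [feature_schema()]; inferred from `features` when
#'   omitted (a column is binary when all its values lie in \{0, 1\}).
#' @return an object of class `site_cohort`.
#' @export
site_cohort <- function(site_id, features, labels, schema = NULL) {
  stopifnot(is.character(site_id), length(site_id) == 1L, nzchar(site_id))
  features <- as.data.frame(features)
  if (nrow(features) < 1L) stop("a site cohort needs at least one sample")
  labels <- as.integer(labels)
  if (length(labels) != nrow(features)) {
    stop("label count must equal the feature row count")
  }
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be binary (0/1) with no missing values")
  }
  if (is.null(schema)) schema <- infer_schema(features)
  check_schema(features, schema)
  structure(
    list(site_id = site_id, features = features, labels = labels,
         schema = schema),
    class = "site_cohort"
  )
}

#' @export
print.site_cohort <- function(x, ...) {
  cat(sprintf(
    "<site_cohort> %s: n = %d, positives = %d (%.1f%%), d = %d\n",
    x$site_id, length(x$labels), sum(x$labels),
    100 * mean(x$labels), length(x$schema$names)
  ))
  invisible(x)
}

#' @keywords internal
infer_schema <- function(features) {
  kinds <- vapply(features, function(col) {
    v <- col[!is.na(col)]
    if (length(v) && all(v %in% c(0, 1))) "binary" else "continuous"
  }, character(1))
  feature_schema(names(features), unname(kinds))
}

#' @keywords internal
check_schema <- function(features, schema) {
  if (!identical(names(features), schema$names)) {
    stop("feature columns do not match the schema (names/order differ)")
  }
  invisible(TRUE)
}

#' A federated cohort: several sites sharing one feature schema
#'
#' @param sites list of [site_cohort()] objects with distinct `site_id`s, all
#'   conforming to the same [feature_schema()].
#' @param schema optional shared schema; defaults to the first site's.
#' @return an object of class `federated_cohort`.
#' @export
federated_cohort <- function(sites, schema = NULL) {
  stopifnot(is.list(sites), length(sites) >= 2L)
  if (!all(vapply(sites, inherits, logical(1), "site_cohort"))) {
    stop("all elements of `sites` must be site_cohort objects")
  }
  ids <- vapply(sites, `[[`, character(1), "site_id")
  if (anyDuplicated(ids)) stop("site_ids must be distinct")
  schema <- schema %||% sites[[1L]]$schema
  for (s in sites) check_schema(s$features, schema)
  names(sites) <- ids
  structure(list(schema = schema, sites = sites), class = "federated_cohort")
}

#' @export
print.federated_cohort <- function(x, ...) {
  n <- vapply(x$sites, function(s) length(s$labels), integer(1))
  pos <- vapply(x$sites, function(s) sum(s$labels), integer(1))
  cat(sprintf(
    "<federated_cohort> %d sites, %d samples (%d positive), %d features\n",
    length(x$sites), sum(n), sum(pos), length(x$schema$names)
  ))
  for (i in seq_along(x$sites)) {
    cat(sprintf("  %-4s n = %5d  incidence = %5.1f%%\n",
                names(x$sites)[i], n[i], 100 * pos[i] / n[i]))
  }
  invisible(x)
}

#' @rdname site_ids
#' @export
site_ids <- function(x) UseMethod("site_ids")

#' Site identifiers of a federated cohort
#'
#' @param x a `federated_cohort`.
#' @return character vector of site ids, in cohort order.
#' @export
site_ids.federated_cohort <- function(x) names(x$sites)

#' Per-site class counts of a federated cohort
#'
#' The sufficient statistics for every aggregation-weighting scheme: per site,
#' total samples, positive count and negative count.
#'
#' @param cohort a `federated_cohort` or a list of `site_cohort`s.
#' @return list of [site_class_counts()] objects, in site order.
#' @seealso [site_weights()]
#' @export
cohort_class_counts <- function(cohort) {
  sites <- if (inherits(cohort, "federated_cohort")) cohort$sites else cohort
  lapply(sites, function(s) {
    site_class_counts(s$site_id, n = length(s$labels), positives = sum(s$labels))
  })
}
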