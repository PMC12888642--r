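#' Aggregation-weighting schemes
#'
#' The five federated prediction-aggregation schemes: `"unweighted"` (equal
#' weights), `"samples"` (weight by site sample count), `"positives"` (by
#' positive-class count), `"minority"` (by minority-class count) and `"mpd"`
#' (by maximum possible diversity, the product of Shannon evenness and sample
#' count).
#'
#' @format character vector of scheme names.
#' @export
WEIGHT_SCHEMES <- c("unweighted", "samples", "positives", "minority", "mpd")

#' Per-site class counts
#'
#' The sufficient statistics for every weighting scheme: total samples,
#' positives and negatives at one site.
#'
#' @param site_id site label.
#' @param n total sample count (>= 0).
#' @param positives positive-class count.
#' @param negatives negative-class count; defaults to `n - positives`.
#' @return an object of class `site_class_counts`.
#' @export
site_class_counts <- function(site_id, n, positives, negatives = n - positives) {
  stopifnot(
    is.character(site_id), length(site_id) == 1L,
    is.numeric(n), is.numeric(positives), is.numeric(negatives),
    length(n) == 1L, length(positives) == 1L, length(negatives) == 1L,
    is.finite(n), is.finite(positives), is.finite(negatives),
    n >= 0, positives >= 0, negatives >= 0
  )
  if (positives + negatives != n) stop("positives + negatives must equal n")
  structure(
    list(site_id = site_id, n = as.numeric(n),
         positives = as.numeric(positives), negatives = as.numeric(negatives)),
    class = "site_class_counts"
  )
}

#' Shannon diversity index
#'
#' `H = -sum(p_j * log(p_j))` over class proportions, with the standard
#' entropy convention `0 * log(0) = 0`. Natural logarithm, so
#' `H` lies in `[0, log(k)]` for `k` classes.
#'
#' @param proportions nonnegative class proportions summing to 1 (within
#'   `1e-9`).
#' @return scalar diversity index.
#' @examples
#' shannon_diversity(c(0.5, 0.5))  # log(2)
#' shannon_diversity(c(1, 0))      # 0
#' @export
shannon_diversity <- function(proportions) {
  if (!is.numeric(proportions) || length(proportions) < 1L ||
      anyNA(proportions) || any(proportions < 0)) {
    stop("`proportions` must be nonnegative and free of missing values")
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("`proportions` must sum to 1 (got ", sum(proportions), ")")
  }
  p <- proportions[proportions > 0]
  -sum(p * log(p))
}

#' Shannon evenness index
#'
#' Diversity normalized by its maximum: `E = H / log(n_classes)`, in
#' `[0, 1]`; 1 for perfectly balanced classes, 0 when a single class holds
#' everything.
#'
#' @param H Shannon diversity index.
#' @param n_classes number of classes (>= 2).
#' @return scalar evenness in `[0, 1]`.
#' @export
shannon_evenness <- function(H, n_classes) {
  stopifnot(is.numeric(H), length(H) == 1L, is.finite(H))
  if (!is.numeric(n_classes) || length(n_classes) != 1L || n_classes < 2) {
    stop("`n_classes` must be at least 2")
  }
  if (H < 0 || H > log(n_classes) + 1e-9) {
    stop("H must lie in [0, log(n_classes)]")
  }
  min(1, H / log(n_classes))
}

#' Maximum possible diversity of a site
#'
#' The mpd weight value `v = E * n`: Shannon evenness of the site's binary
#' class proportions times its sample count. It combines size and balance —
#' `v = n` for a perfectly balanced site, `v = 0` when one class is absent —
#' penalizing sites whose data are heavily dominated by one class.
#'
#' @param counts a [site_class_counts()] with `n >= 1`.
#' @return an object of class `site_value` (fields `site_id`, `value`).
#' @examples
#' mpd_value(site_class_counts("H01", n = 5033, positives = 953))
#' @export
mpd_value <- function(counts) {
  stopifnot(inherits(counts, "site_class_counts"))
  if (counts$n < 1) stop("mpd requires n >= 1")
  H <- shannon_diversity(c(counts$positives, counts$negatives) / counts$n)
  v <- shannon_evenness(H, 2L) * counts$n
  structure(list(site_id = counts$site_id, value = v), class = "site_value")
}

#' @export
print.site_value <- function(x, ...) {
  cat(sprintf("<site_value> %s: %.3f\n", x$site_id, x$value))
  invisible(x)
}

#' Raw weighting value of a site under a scheme
#'
#' The unnormalized per-site value `v_i` that, divided by its total over
#' sites, becomes the aggregation weight: the sample count (`samples`), the
#' positive count (`positives`), the minority-class count (`minority`), the
#' maximum possible diversity (`mpd`), or 1 for every site (`unweighted`).
#'
#' @param scheme one of [WEIGHT_SCHEMES].
#' @param counts a [site_class_counts()].
#' @return an object of class `site_value`.
#' @export
site_value <- function(scheme, counts) {
  scheme <- match.arg(scheme, WEIGHT_SCHEMES)
  stopifnot(inherits(counts, "site_class_counts"))
  v <- switch(scheme,
    unweighted = 1,
    samples    = counts$n,
    positives  = counts$positives,
    minority   = min(counts$positives, counts$negatives),
    mpd        = mpd_value(counts)$value
  )
  structure(list(site_id = counts$site_id, value = v), class = "site_value")
}

#' Normalize per-site values into aggregation weights
#'
#' `w_i = v_i / sum(v)`: nonnegative weights summing to one, in site order.
#'
#' @param values list of `site_value` objects (one per site, order kept).
#' @param scheme the [WEIGHT_SCHEMES] name the values came from.
#' @return an object of class `weight_vector` (fields `scheme`, `site_id`,
#'   `weights`; weights named by site).
#' @export
normalize_weights <- function(values, scheme) {
  scheme <- match.arg(scheme, WEIGHT_SCHEMES)
  stopifnot(is.list(values), length(values) >= 1L)
  if (!all(vapply(values, inherits, logical(1), "site_value"))) {
    stop("`values` must be a list of site_value objects")
  }
  v <- unname(vapply(values, `[[`, numeric(1), "value"))
  ids <- unname(vapply(values, `[[`, character(1), "site_id"))
  if (anyNA(v) || any(!is.finite(v)) || any(v < 0)) {
    stop("site values must be finite and nonnegative")
  }
  total <- sum(v)
  if (total <= 0) {
    stop("all site values are zero under scheme '", scheme,
         "': no usable site to weight")
  }
  w <- v / total
  names(w) <- ids
  structure(list(scheme = scheme, site_id = ids, weights = w),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("<weight_vector> scheme = %s\n", x$scheme))
  print(round(x$weights, 3))
  invisible(x)
}

#' Compute aggregation weights for a set of sites
#'
#' Convenience wrapper: per-site values and normalized weights for one scheme
#' (or all five), from a list of [site_class_counts()], a
#' [federated_cohort()], or a data.frame with columns `site_id`, `n`,
#' `positives`.
#'
#' @param counts class counts in any of the forms above.
#' @param scheme one of [WEIGHT_SCHEMES], or `"all"`.
#' @return for one scheme, a data.frame `(site_id, scheme, value, weight)`;
#'   for `"all"`, those data.frames row-bound over schemes.
#' @examples
#' site_weights(delirium_site_profile(), "mpd")
#' @export
site_weights <- function(counts, scheme = "all") {
  counts <- as_counts_list(counts)
  schemes <- if (identical(scheme, "all")) WEIGHT_SCHEMES
             else match.arg(scheme, WEIGHT_SCHEMES)
  out <- lapply(schemes, function(sc) {
    vals <- lapply(counts, function(cc) site_value(sc, cc))
    wv <- normalize_weights(vals, sc)
    data.frame(
      site_id = wv$site_id,
      scheme = sc,
      value = vapply(vals, `[[`, numeric(1), "value"),
      weight = unname(wv$weights),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' @keywords internal
as_counts_list <- function(counts) {
  if (inherits(counts, "federated_cohort")) return(cohort_class_counts(counts))
  if (is.data.frame(counts)) {
    stopifnot(all(c("site_id", "n", "positives") %in% names(counts)))
    return(lapply(seq_len(nrow(counts)), function(i) {
      site_class_counts(counts$site_id[i], counts$n[i], counts$positives[i])
    }))
  }
  if (is.list(counts) &&
      all(vapply(counts, inherits, logical(1), "site_class_counts"))) {
    return(counts)
  }
  stop("cannot interpret `counts` as per-site class counts")
}
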